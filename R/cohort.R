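# Synthetic cohort generation: truncated-normal marginals per group coupled
# to catheter mPAP through a Gaussian copula with specified rank
# correlations, plus clinical subgroup structure, binary late-gadolinium-
# enhancement annotations and per-modality measurement subsets.

# ---- truncated normal helpers ------------------------------------------

# quantile of N(mu, sigma) truncated to [lower, upper]
qtruncnorm <- function(u, mu, sigma, lower = -Inf, upper = Inf) {
  pa <- pnorm((lower - mu) / sigma)
  pb <- pnorm((upper - mu) / sigma)
  mu + sigma * qnorm(pa + u * (pb - pa))
}

# mean and sd of N(mu, sigma) truncated to [lower, upper]
truncnorm_moments <- function(mu, sigma, lower = -Inf, upper = Inf) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  pa <- dnorm(a); pb <- dnorm(b)
  apa <- if (is.finite(a)) a * pa else 0
  bpb <- if (is.finite(b)) b * pb else 0
  m <- mu + sigma * (pa - pb) / Z
  v <- sigma^2 * (1 + (apa - bpb) / Z - ((pa - pb) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# find underlying (mu, sigma) whose truncated moments equal the targets,
# so truncation does not bias the requested marginal mean/sd
match_truncnorm <- function(mean, sd, lower = -Inf, upper = Inf) {
  a <- if (is.finite(lower)) (lower - mean) / sd else -Inf
  b <- if (is.finite(upper)) (upper - mean) / sd else Inf
  if (a < -6 && b > 6) return(c(mu = mean, sigma = sd))  # truncation negligible
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), lower, upper)
    (mo[["mean"]] - mean)^2 / sd^2 + (mo[["sd"]] - sd)^2 / sd^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  if (fit$value > 1e-6) {
    rhcmr_error(
      sprintf("cannot match truncated-normal moments mean=%g sd=%g on [%g, %g]",
              mean, sd, lower, upper),
      "rhcmr_infeasible_marginal")
  }
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Spearman rank correlation -> latent Gaussian copula correlation
spearman_to_latent <- function(rho) {
  if (any(abs(rho) >= 1)) {
    rhcmr_error("rank correlations must lie in (-1, 1)",
                "rhcmr_infeasible_correlation")
  }
  2 * sin(pi * rho / 6)
}

# ---- cohort specification ----------------------------------------------

#' Load a synthetic-cohort specification
#'
#' Reads the versioned YAML encoding of the cohort structure: group sizes,
#' per-group truncated-normal marginals for every metric, within-group rank
#' correlations with mPAP, late-gadolinium-enhancement rates, clinical
#' subgroup mix, and per-modality measurement subset fractions.  The
#' packaged default describes a pulmonary-hypertension referral cohort of
#' 39 'no PH' and 194 PH patients.
#'
#' @param path YAML file; default the packaged specification.
#' @param n_no_ph,n_ph optional group-size overrides.
#' @return an object of class `cohort_spec` (named list mirroring the
#'   YAML).
#' @export
cohort_spec <- function(path = NULL, n_no_ph = NULL, n_ph = NULL) {
  path <- path %||% system.file("extdata", "cohort_defaults.yaml",
                                package = "rhcmr", mustWork = TRUE)
  spec <- yaml::read_yaml(path)
  if (!is.null(n_no_ph)) spec$groups$NO_PH$n <- as.integer(n_no_ph)
  if (!is.null(n_ph)) spec$groups$PH$n <- as.integer(n_ph)
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  stopifnot(!is.null(spec$groups$NO_PH), !is.null(spec$groups$PH))
  for (g in spec$groups) {
    stopifnot(g$n >= 1, g$mpap$sd > 0, g$lge_rate >= 0, g$lge_rate <= 1)
  }
  all_metrics <- c(spec$metrics, spec$echo_metrics,
                   spec$phase_contrast_metrics)
  for (nm in names(all_metrics)) {
    m <- all_metrics[[nm]]
    if (m$no_ph[2] <= 0 || m$ph[2] <= 0) {
      rhcmr_error(sprintf("metric %s: sd must be positive", nm),
                  "rhcmr_invalid_spec")
    }
    if (abs(m$r_mpap) >= 1) {
      rhcmr_error(sprintf("metric %s: correlation must lie in (-1, 1)", nm),
                  "rhcmr_infeasible_correlation")
    }
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  nm <- length(x$metrics) + length(x$echo_metrics) +
    length(x$phase_contrast_metrics)
  cat(sprintf("<cohort_spec v%s> NO_PH n=%d, PH n=%d; %d metrics; %d PH subgroups\n",
              x$version, x$groups$NO_PH$n, x$groups$PH$n, nm,
              length(x$subgroups)))
  invisible(x)
}

# ---- generation ---------------------------------------------------------

# draw one group's block: mPAP by inverse-CDF of its truncated normal, each
# metric from the Gaussian copula with its latent correlation to the mPAP
# latent score, through its own moment-matched truncated marginal
draw_group <- function(n, group_cfg, metric_cfgs, which_col) {
  z1 <- rnorm(n)
  mp <- group_cfg$mpap
  mp_lo <- mp$lower %||% -Inf
  mp_hi <- mp$upper %||% Inf
  mp_par <- match_truncnorm(mp$mean, mp$sd, mp_lo, mp_hi)
  mpap <- qtruncnorm(pnorm(z1), mp_par[["mu"]], mp_par[["sigma"]],
                     mp_lo, mp_hi)
  out <- list(mpap = mpap)
  for (nm in names(metric_cfgs)) {
    cfg <- metric_cfgs[[nm]]
    ms <- cfg[[which_col]]
    lat <- spearman_to_latent(cfg$r_mpap)
    z2 <- lat * z1 + sqrt(1 - lat^2) * rnorm(n)
    if (identical(cfg$dist, "lognormal")) {
      # moment-matched lognormal for strongly right-skewed positives
      s2 <- log(1 + (ms[2] / ms[1])^2)
      out[[nm]] <- stats::qlnorm(pnorm(z2), log(ms[1]) - s2 / 2, sqrt(s2))
    } else {
      lo <- cfg$lower %||% -Inf
      hi <- cfg$upper %||% Inf
      par <- match_truncnorm(ms[1], ms[2], lo, hi)
      out[[nm]] <- qtruncnorm(pnorm(z2), par[["mu"]], par[["sigma"]], lo, hi)
    }
  }
  out
}

# deterministic proportional allocation of subgroup counts (largest
# remainder), then a random permutation over patients
allocate_subgroups <- function(n, counts) {
  p <- unlist(counts) / sum(unlist(counts))
  base <- floor(n * p)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * p - base
    base[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      base[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  sample(rep(names(counts), times = base))
}

#' Generate a synthetic patient cohort
#'
#' Draws a cohort with the configured two-group structure.  Within each
#' group, catheter mPAP comes from a truncated normal (the 'no PH' group
#' truncated below 25 mmHg, the PH group at or above it, so the group label
#' satisfies the mPAP >= 25 mmHg definition by construction) and every
#' metric is drawn through a Gaussian copula with the specified rank
#' correlation to mPAP and a moment-matched truncated-normal marginal.
#' Late gadolinium enhancement is a Bernoulli draw at the group rate within
#' its measured subset; phase-contrast and echo metrics are present only in
#' their measurement subsets.  Identical seeds give identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer RNG seed.
#' @param n_non_diagnostic number of additional records flagged
#'   `non_diagnostic = TRUE` (excluded from analysis by the pipeline),
#'   emulating scans of inadequate quality.
#' @return a data frame of class `rhcmr_cohort`, one row per patient:
#'   `patient_id`, `group`, `subgroup`, `non_diagnostic`, `mpap`, `bsa`,
#'   `sex`, haemodynamic and CMR metric columns, `trjv`, `rap_estimate`,
#'   derived `echo_mpap`, phase-contrast columns, and `lge_present`
#'   (`NA` outside the measured subset).
#' @export
#' @examples
#' coh <- make_cohort(cohort_spec(), seed = 7)
#' table(coh$group)
make_cohort <- function(spec, seed = 1, n_non_diagnostic = 0) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))

  n_no <- spec$groups$NO_PH$n
  n_ph <- spec$groups$PH$n
  extra_ph <- extra_no <- 0L
  if (n_non_diagnostic > 0) {
    # extras follow the cohort mix so excluded scans resemble included ones
    extra_ph <- rbinom(1, n_non_diagnostic, n_ph / (n_ph + n_no))
    extra_no <- n_non_diagnostic - extra_ph
  }

  all_metrics <- c(spec$metrics, spec$echo_metrics,
                   spec$phase_contrast_metrics)
  blocks <- list(
    NO_PH = draw_group(n_no + extra_no, spec$groups$NO_PH, all_metrics,
                       "no_ph"),
    PH = draw_group(n_ph + extra_ph, spec$groups$PH, all_metrics, "ph"))

  df <- do.call(rbind, lapply(names(blocks), function(g) {
    b <- as.data.frame(blocks[[g]])
    b$group <- g
    b
  }))
  n_tot <- nrow(df)
  df$non_diagnostic <- FALSE
  if (extra_no > 0) {
    df$non_diagnostic[n_no + seq_len(extra_no)] <- TRUE
  }
  if (extra_ph > 0) {
    idx_ph <- which(df$group == "PH")
    df$non_diagnostic[idx_ph[seq_along(idx_ph) > n_ph]] <- TRUE
  }

  df$subgroup <- "NONE"
  idx_ph <- which(df$group == "PH")
  df$subgroup[idx_ph] <- allocate_subgroups(length(idx_ph), spec$subgroups)

  df$sex <- NA_character_
  for (g in names(spec$female_rate)) {
    idx <- which(df$group == g)
    df$sex[idx] <- ifelse(runif(length(idx)) < spec$female_rate[[g]],
                          "F", "M")
  }
  bs <- spec$bsa
  par <- match_truncnorm(bs$mean, bs$sd, bs$lower, bs$upper)
  df$bsa <- qtruncnorm(runif(n_tot), par[["mu"]], par[["sigma"]],
                       bs$lower, bs$upper)

  # measurement subsets are defined over the analysed (diagnostic) records
  analysed <- which(!df$non_diagnostic)
  n_pc <- round(spec$phase_contrast_frac * length(analysed))
  pc_idx <- sample(analysed, n_pc)
  for (nm in names(spec$phase_contrast_metrics)) {
    df[[nm]][setdiff(seq_len(n_tot), pc_idx)] <- NA_real_
  }

  n_echo <- round(spec$echo_frac * length(analysed))
  echo_idx <- sample(analysed, n_echo)
  df$rap_estimate <- NA_real_
  for (g in c("NO_PH", "PH")) {
    idx <- intersect(echo_idx, which(df$group == g))
    df$rap_estimate[idx] <- sample(unlist(spec$rap_levels), length(idx),
                                   replace = TRUE,
                                   prob = unlist(spec$rap_probs[[g]]))
  }
  df$trjv[setdiff(seq_len(n_tot), echo_idx)] <- NA_real_
  df$echo_mpap <- NA_real_
  ok <- !is.na(df$trjv) & !is.na(df$rap_estimate)
  df$echo_mpap[ok] <- echo_mpap(pmax(df$trjv[ok], 0), df$rap_estimate[ok])

  df$lge_present <- NA
  for (g in c("NO_PH", "PH")) {
    cfg <- spec$groups[[g]]
    idx <- intersect(analysed, which(df$group == g))
    n_meas <- round(cfg$lge_measured_frac * length(idx))
    meas <- sample(idx, n_meas)
    df$lge_present[meas] <- runif(n_meas) < cfg$lge_rate
  }

  # stable presentation order: analysed records first is not imposed; keep
  # draw order but give reproducible ids
  df$patient_id <- sprintf("P%04d", seq_len(n_tot))
  front <- c("patient_id", "group", "subgroup", "non_diagnostic", "sex",
             "bsa", "mpap")
  df <- df[, c(front, setdiff(names(df), front))]
  rownames(df) <- NULL
  class(df) <- c("rhcmr_cohort", "data.frame")
  df
}

#' Read or write a cohort table as CSV
#'
#' One row per patient; columns as produced by [make_cohort()].
#'
#' @param path CSV file path.
#' @return `read_cohort_csv()` returns the cohort data frame;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "group", "mpap") %in% names(df))) {
    rhcmr_error("cohort CSV must carry patient_id, group and mpap columns",
                "rhcmr_invalid_cohort")
  }
  if ("lge_present" %in% names(df)) df$lge_present <- as.logical(df$lge_present)
  if ("non_diagnostic" %in% names(df)) {
    df$non_diagnostic <- as.logical(df$non_diagnostic)
  }
  class(df) <- c("rhcmr_cohort", "data.frame")
  df
}

#' @rdname read_cohort_csv
#' @param cohort a cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
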