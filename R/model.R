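#' Build the density-model input table
#'
#' One row per included, modelled cell per marker: the shell count, the shell
#' volume (offset), the ChAT/NOS class and the subject/ganglion grouping.
#' ChAT-/NOS- cells are dropped (too few for meaningful comparison); the three
#' remaining classes are modelled.
#'
#' @param records density tibble from [compute_densities()] (possibly several
#'   scenes bound together).
#' @param typed typed-cell tibble with `cell_id`, `cell_type`, `included`.
#'   When omitted, `records$cell_type` is used directly.
#' @return A tibble `subj`, `gang`, `cell_id`, `cell_type` (factor over the
#'   three modelled classes), `marker` (factor TH/ENK), `count`, `volume`.
#' @export
build_model_input <- function(records, typed = NULL) {
  records <- tibble::as_tibble(records)
  if (!is.null(typed)) {
    typed <- tibble::as_tibble(typed)
    if ("included" %in% names(typed)) typed <- dplyr::filter(typed, .data$included)
    records <- records |>
      dplyr::select(-dplyr::any_of("cell_type")) |>
      dplyr::inner_join(typed[c("cell_id", "cell_type")], by = "cell_id")
  }
  miss <- is.na(records$cell_type)
  if (any(miss))
    rlang::abort(sprintf("cell '%s' has a density record but no cell type",
                         records$cell_id[which(miss)[1]]),
                 class = "perishell_model_error")
  if (any(records$shell_volume_um3 <= 0))
    rlang::abort("non-positive shell volume in model input", class = "perishell_model_error")
  records |>
    dplyr::filter(as.character(.data$cell_type) %in% modelled_cell_types) |>
    dplyr::transmute(
      subj = as.character(.data$subject_id),
      gang = paste(.data$subject_id, .data$ganglion_id, sep = ":"),
      cell_id = .data$cell_id,
      cell_type = factor(as.character(.data$cell_type), levels = modelled_cell_types),
      marker = factor(.data$marker, levels = varicosity_markers),
      count = as.integer(.data$count),
      volume = .data$shell_volume_um3)
}

nb_glmm_jags_model <- "model {
  for (i in 1:N) {
    y[i] ~ dnegbin(pr[i], phi[cellm[i]])
    pr[i] <- phi[cellm[i]] / (phi[cellm[i]] + mu[i])
    log(mu[i]) <- beta[cellm[i]] + a[subj[i]] + e[subj[i], cellm[i]] +
                  b[gang[i]] + f[gang[i], cellm[i]] + logV[i]
  }
  for (k in 1:K) {
    beta[k] ~ dnorm(0, 1)
    gam[k] ~ dnorm(0, 1)
    phi[k] <- exp(gam[k])
    sd_subj_cell[k] ~ dnorm(0, 1) T(0,)
    sd_gang_cell[k] ~ dnorm(0, 1) T(0,)
    tau_e[k] <- pow(sd_subj_cell[k], -2)
    tau_f[k] <- pow(sd_gang_cell[k], -2)
    for (s in 1:S) { e[s, k] ~ dnorm(0, tau_e[k]) }
    for (g in 1:G) { f[g, k] ~ dnorm(0, tau_f[k]) }
    beta_pop[k] <- beta[k] + mean(a) + mean(e[, k]) + mean(b) + mean(f[, k])
  }
  sd_subj ~ dnorm(0, 1) T(0,)
  sd_gang ~ dnorm(0, 1) T(0,)
  tau_a <- pow(sd_subj, -2)
  tau_b <- pow(sd_gang, -2)
  for (s in 1:S) { a[s] ~ dnorm(0, tau_a) }
  for (g in 1:G) { b[g] ~ dnorm(0, tau_b) }
}"

#' Fit the negative-binomial mixed model of shell counts
#'
#' Bayesian negative-binomial regression of per-cell shell counts with log
#' link and log shell volume as offset, so coefficients are log densities.
#' Cell-mean coding: one coefficient per cell type x marker combination (no
#' global intercept). The shape parameter gets its own log-linear submodel
#' over the same six combinations (Var = mu + mu^2/phi). Random effects are
#' nested subject and subject:ganglion terms with a compound-symmetry
#' structure: a shared intercept plus independent per-combination deviations
#' at each level, giving cells of the same subject (ganglion) correlated
#' density variation that is partially pooled across combinations. Priors:
#' normal(0,1) on the mean and shape coefficients, half-normal(0,1) on all
#' random-effect scales. Sampling is by MCMC (JAGS); population coefficients
#' are monitored in their identifiable "swept" form (coefficient plus the
#' random-effect sample means), on which densities and ratios are based.
#'
#' @param rows model input from [build_model_input()].
#' @param chains number of MCMC chains (default 4).
#' @param warmup warmup (adaptation + burn-in) iterations per chain
#'   (default 1000).
#' @param draws retained iterations per chain (default 1000).
#' @param seed integer seed governing all chains.
#' @param rhat_warn warn when any monitored Rhat exceeds this (default 1.05).
#' @param quiet suppress sampler progress.
#' @return An object of class `nb_glmm`: draws of the six population log
#'   densities (`beta_pop`), shape coefficients (`gam`), random-effect scales,
#'   plus Rhat per parameter, effective sizes and the sampler settings.
#' @export
fit_nb_glmm <- function(rows, chains = 4, warmup = 1000, draws = 1000,
                        seed = 1, rhat_warn = 1.05, quiet = TRUE) {
  rows <- tibble::as_tibble(rows)
  if (length(unique(rows$subj)) < 2)
    rlang::abort("need at least 2 subjects", class = "perishell_model_error")
  if (length(unique(as.character(rows$cell_type))) < 2)
    rlang::abort("need at least 2 cell types", class = "perishell_model_error")
  if (any(rows$volume <= 0) || any(rows$count < 0) || any(!is.finite(rows$count)))
    rlang::abort("invalid counts or volumes", class = "perishell_model_error")

  type_f <- factor(as.character(rows$cell_type), levels = modelled_cell_types)
  marker_f <- factor(as.character(rows$marker), levels = varicosity_markers)
  combo <- interaction(type_f, marker_f, sep = " x ", lex.order = FALSE)
  combo_levels <- levels(combo)
  present <- table(combo)
  if (any(present == 0))
    rlang::abort(sprintf("no rows for combination(s): %s",
                         paste(names(present)[present == 0], collapse = ", ")),
                 class = "perishell_model_error")

  subj_f <- factor(rows$subj)
  gang_f <- factor(rows$gang)
  dat <- list(y = rows$count, cellm = as.integer(combo),
              subj = as.integer(subj_f), gang = as.integer(gang_f),
              logV = log(rows$volume), N = nrow(rows),
              K = length(combo_levels), S = nlevels(subj_f), G = nlevels(gang_f))

  set.seed(seed)
  inits <- lapply(seq_len(chains), function(i)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = sample.int(.Machine$integer.max, 1)))
  adapt <- max(200L, min(500L, warmup %/% 2))
  burn <- max(0L, warmup - adapt)
  jm <- rjags::jags.model(textConnection(nb_glmm_jags_model), data = dat,
                          n.chains = chains, n.adapt = adapt, inits = inits,
                          quiet = quiet)
  if (burn > 0) stats::update(jm, burn, progress.bar = "none")
  monitors <- c("beta_pop", "gam", "sd_subj", "sd_gang",
                "sd_subj_cell", "sd_gang_cell")
  samp <- rjags::coda.samples(jm, monitors, n.iter = draws, progress.bar = "none")

  rhat <- tryCatch(
    coda::gelman.diag(samp, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1],
    error = function(e) stats::setNames(rep(NA_real_, ncol(samp[[1]])),
                                        colnames(samp[[1]])))
  ess <- coda::effectiveSize(samp)
  if (any(rhat > rhat_warn, na.rm = TRUE))
    warning(sprintf("Rhat above %.2f for: %s", rhat_warn,
                    paste(names(rhat)[which(rhat > rhat_warn)], collapse = ", ")),
            call. = FALSE)

  draws_mat <- do.call(rbind, lapply(samp, as.matrix))
  structure(list(
    draws = draws_mat, combo_levels = combo_levels,
    rhat = rhat, ess = ess, divergences = NA_integer_,
    settings = list(chains = chains, warmup = warmup, draws = draws, seed = seed),
    data_info = list(n_rows = nrow(rows), n_subjects = nlevels(subj_f),
                     n_ganglia = nlevels(gang_f),
                     n_cells = length(unique(rows$cell_id)))),
    class = "nb_glmm")
}

combo_name <- function(cell_type, marker) paste(cell_type, marker, sep = " x ")

combo_column <- function(fit, cell_type, marker) {
  cn <- combo_name(cell_type, marker)
  k <- match(cn, fit$combo_levels)
  if (is.na(k))
    rlang::abort(sprintf("unknown cell type x marker combination: %s", cn),
                 class = "perishell_model_error")
  fit$draws[, sprintf("beta_pop[%d]", k)]
}

#' Posterior mean density for a cell type and marker
#'
#' The population-level mean varicosity density (random effects at their
#' population value), i.e. exp of the relevant coefficient draws times 1,000,
#' in varicosities per 1,000 um^3.
#'
#' @param fit an `nb_glmm` fit.
#' @param cell_type one of the modelled ChAT/NOS classes.
#' @param marker `"TH"` or `"ENK"`.
#' @return A tibble `cell_type`, `marker`, `median`, `ci_lo`, `ci_hi`
#'   (equal-tailed 95% credible interval), densities per 1,000 um^3.
#' @export
mean_density <- function(fit, cell_type, marker) {
  stopifnot(inherits(fit, "nb_glmm"))
  dens <- exp(combo_column(fit, cell_type, marker)) * 1000
  q <- stats::quantile(dens, c(0.5, 0.025, 0.975), names = FALSE)
  tibble::tibble(cell_type = cell_type, marker = marker,
                 median = q[1], ci_lo = q[2], ci_hi = q[3])
}

#' @rdname mean_density
#' @export
mean_densities <- function(fit) {
  grid <- tidyr::expand_grid(cell_type = modelled_cell_types,
                             marker = varicosity_markers)
  purrr::pmap_dfr(grid, function(cell_type, marker)
    mean_density(fit, cell_type, marker))
}

#' Posterior density ratio between two cell types
#'
#' Draw-wise ratio of mean densities for one marker: exp(beta_a - beta_b).
#' Reported as posterior median with the equal-tailed 95% credible interval,
#' the posterior probability that the ratio exceeds 1, and a `significant`
#' flag set when the interval excludes 1.
#'
#' @param fit an `nb_glmm` fit.
#' @param marker `"TH"` or `"ENK"`.
#' @param type_a,type_b numerator and denominator cell types.
#' @return A tibble `marker`, `type_a`, `type_b`, `median`, `ci_lo`, `ci_hi`,
#'   `pr_gt_1`, `significant`.
#' @export
density_ratio <- function(fit, marker, type_a, type_b) {
  stopifnot(inherits(fit, "nb_glmm"))
  if (identical(type_a, type_b)) {
    return(tibble::tibble(marker = marker, type_a = type_a, type_b = type_b,
                          median = 1, ci_lo = 1, ci_hi = 1, pr_gt_1 = 0,
                          significant = FALSE))
  }
  r <- exp(combo_column(fit, type_a, marker) - combo_column(fit, type_b, marker))
  q <- stats::quantile(r, c(0.5, 0.025, 0.975), names = FALSE)
  tibble::tibble(marker = marker, type_a = type_a, type_b = type_b,
                 median = q[1], ci_lo = q[2], ci_hi = q[3],
                 pr_gt_1 = mean(r > 1),
                 significant = q[2] > 1 || q[3] < 1)
}

#' @rdname density_ratio
#' @details `density_ratios()` reports the three standard contrasts
#'   (ChAT+/NOS- vs ChAT-/NOS+, ChAT+/NOS- vs ChAT+/NOS+, ChAT-/NOS+ vs
#'   ChAT+/NOS+) for each marker.
#' @export
density_ratios <- function(fit) {
  contrasts <- list(c("ChAT+/NOS-", "ChAT-/NOS+"),
                    c("ChAT+/NOS-", "ChAT+/NOS+"),
                    c("ChAT-/NOS+", "ChAT+/NOS+"))
  purrr::map_dfr(varicosity_markers, function(mk)
    purrr::map_dfr(contrasts, function(ct)
      density_ratio(fit, mk, ct[1], ct[2])))
}

#' @export
print.nb_glmm <- function(x, ...) {
  cat(sprintf("<nb_glmm: %d rows, %d subjects, %d ganglia, %d cells>\n",
              x$data_info$n_rows, x$data_info$n_subjects,
              x$data_info$n_ganglia, x$data_info$n_cells))
  cat(sprintf("  %d chains x %d draws (warmup %d), max Rhat %.3f\n",
              x$settings$chains, x$settings$draws, x$settings$warmup,
              max(x$rhat, na.rm = TRUE)))
  print(mean_densities(x))
  invisible(x)
}

#' Tidy and glance methods for the density model
#'
#' `tidy()` returns one row per monitored parameter with posterior median,
#' equal-tailed 95% interval, Rhat and effective sample size; `glance()` a
#' one-row model summary.
#'
#' @param x an `nb_glmm` fit.
#' @param ... unused.
#' @export
tidy.nb_glmm <- function(x, ...) {
  qs <- t(apply(x$draws, 2, stats::quantile, probs = c(0.5, 0.025, 0.975)))
  tibble::tibble(term = colnames(x$draws),
                 estimate = qs[, 1], conf.low = qs[, 2], conf.high = qs[, 3],
                 rhat = unname(x$rhat[colnames(x$draws)]),
                 ess = unname(x$ess[colnames(x$draws)]))
}

#' @rdname tidy.nb_glmm
#' @export
glance.nb_glmm <- function(x, ...) {
  tibble::tibble(nobs = x$data_info$n_rows,
                 n_subjects = x$data_info$n_subjects,
                 n_ganglia = x$data_info$n_ganglia,
                 chains = x$settings$chains,
                 draws_per_chain = x$settings$draws,
                 max_rhat = max(x$rhat, na.rm = TRUE),
                 divergences = x$divergences)
}

#' Morphometric one-way ANOVA with Tukey contrasts
#'
#' Compares cell surface area or volume across the four ChAT/NOS classes with
#' a one-way ANOVA followed by Tukey's honest significant differences. The
#' unit of analysis defaults to per-ganglion type means (cells within a
#' ganglion are not independent); set `unit_of_analysis = "cell"` to use
#' individual cells. The unit used is always recorded in the output.
#'
#' @param data tibble with `cell_type`, the `measure` column, and (for the
#'   ganglion-mean unit) `subject_id`/`ganglion_id`.
#' @param measure `"surface_area_um2"` or `"volume_um3"` (any numeric column).
#' @param unit_of_analysis `"ganglion_mean"` (default) or `"cell"`.
#' @return A list of class `morpho_anova`: `anova` (tibble: F, dfs, p),
#'   `tukey` (tibble per pair: difference, 95% CI, adjusted p),
#'   `unit_of_analysis`, `measure`.
#' @export
morphometric_anova <- function(data, measure = "volume_um3",
                               unit_of_analysis = c("ganglion_mean", "cell")) {
  unit_of_analysis <- match.arg(unit_of_analysis)
  data <- tibble::as_tibble(data)
  if (!measure %in% names(data))
    rlang::abort(sprintf("measure column '%s' not found", measure),
                 class = "perishell_model_error")
  if ("included" %in% names(data)) data <- dplyr::filter(data, .data$included)
  df <- if (unit_of_analysis == "ganglion_mean") {
    data |>
      dplyr::group_by(.data$subject_id, .data$ganglion_id, .data$cell_type) |>
      dplyr::summarise(value = mean(.data[[measure]]), .groups = "drop")
  } else {
    dplyr::transmute(data, cell_type = .data$cell_type, value = .data[[measure]])
  }
  df$cell_type <- factor(as.character(df$cell_type), levels = cell_types)
  df <- df[!is.na(df$value) & !is.na(df$cell_type), ]
  sizes <- table(df$cell_type)
  if (sum(sizes >= 2) < 2)
    rlang::abort("need at least 2 cell types with at least 2 units each",
                 class = "perishell_model_error")
  if (stats::sd(df$value) == 0)
    rlang::abort("all values identical: zero variance", class = "perishell_model_error")
  fit <- stats::aov(value ~ cell_type, data = df)
  at <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit)$cell_type
  list(anova = tibble::tibble(F = at$`F value`[1], df1 = at$Df[1], df2 = at$Df[2],
                              p_value = at$`Pr(>F)`[1]),
       tukey = tibble::tibble(pair = rownames(tk), diff = tk[, "diff"],
                              ci_lo = tk[, "lwr"], ci_hi = tk[, "upr"],
                              p_adj = tk[, "p adj"]),
       unit_of_analysis = unit_of_analysis, measure = measure) |>
    structure(class = "morpho_anova")
}

#' @export
print.morpho_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA of %s (unit: %s): F(%d,%d) = %.2f, p = %.3g\n",
              x$measure, x$unit_of_analysis, x$anova$df1, x$anova$df2,
              x$anova$F, x$anova$p_value))
  print(x$tukey)
  invisible(x)
}
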