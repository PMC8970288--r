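# Simulate model-input rows directly from the NB mixed model (no geometry),
# for fast model-level tests. Densities are per 1,000 um^3.
simulate_rows <- function(n_subjects = 7, ganglia = 2, cells = 35,
                          dens = matrix(c(7.43, 5.59, 6.02, 19.52, 12.99, 13.22), 3),
                          sd_subj = 0.2, sd_gang = 0.1, phi = 3, seed = 1) {
  set.seed(seed)
  rows <- list()
  cid <- 0
  for (s in seq_len(n_subjects)) {
    bs <- rnorm(1, 0, sd_subj)
    for (g in seq_len(ganglia)) {
      bg <- rnorm(1, 0, sd_gang)
      n <- max(2, rpois(1, cells))
      type <- sample(1:3, n, TRUE, prob = c(0.41, 0.46, 0.13))
      vol <- rlnorm(n, log(6000), 0.3)
      for (mk in 1:2) {
        mu <- dens[cbind(type, mk)] / 1000 * vol * exp(bs + bg)
        rows[[length(rows) + 1]] <- tibble::tibble(
          subj = sprintf("S%d", s), gang = sprintf("S%d:G%d", s, g),
          cell_id = sprintf("S%dG%d_c%03d", s, g, seq_len(n) + cid),
          cell_type = factor(modelled_cell_types[type], levels = modelled_cell_types),
          marker = factor(varicosity_markers[mk], levels = varicosity_markers),
          count = rnbinom(n, mu = mu, size = phi), volume = vol)
      }
      cid <- cid + n
    }
  }
  dplyr::bind_rows(rows)
}

# A degenerate hand-built fit whose draws are fully specified.
fake_fit <- function(draws_list) {
  combos <- as.vector(outer(modelled_cell_types, varicosity_markers,
                            function(a, b) paste(a, b, sep = " x ")))
  mat <- do.call(cbind, draws_list)
  colnames(mat) <- sprintf("beta_pop[%d]", seq_along(draws_list))
  structure(list(draws = mat, combo_levels = combos,
                 rhat = stats::setNames(rep(1, ncol(mat)), colnames(mat)),
                 ess = stats::setNames(rep(nrow(mat), ncol(mat)), colnames(mat)),
                 divergences = NA_integer_,
                 settings = list(chains = 1, warmup = 0, draws = nrow(mat), seed = 0),
                 data_info = list(n_rows = 0, n_subjects = 0, n_ganglia = 0,
                                  n_cells = 0)),
            class = "nb_glmm")
}

test_that("model input drops ChAT-/NOS- cells and keeps two rows per cell", {
  counts <- c(190, 205, 58, 33)
  typed <- tibble::tibble(cell_id = sprintf("c%03d", 1:486),
                          cell_type = rep(cell_types, counts), included = TRUE)
  rec <- tidyr::expand_grid(cell_id = typed$cell_id,
                            marker = varicosity_markers) |>
    dplyr::mutate(subject_id = "S1", ganglion_id = "G1", count = 5L,
                  shell_volume_um3 = 6000,
                  density_per_1000um3 = 1000 * 5 / 6000)
  rows <- build_model_input(rec, typed)
  expect_equal(nrow(rows), 906)  # 453 modelled cells x 2 markers
  expect_equal(length(unique(rows$cell_id)), 453)
  expect_setequal(as.character(unique(rows$cell_type)), modelled_cell_types)
  expect_equal(unname(table(rows$marker)["TH"]), 453, ignore_attr = TRUE)
})

test_that("model input contract errors: zero volume, missing type, empty input", {
  rec <- tibble::tibble(subject_id = "S", ganglion_id = "G", cell_id = "c1",
                        cell_type = "ChAT+/NOS-", marker = "TH", count = 1L,
                        shell_volume_um3 = 0, density_per_1000um3 = Inf)
  expect_error(build_model_input(rec), class = "perishell_model_error")
  rec2 <- dplyr::mutate(rec, shell_volume_um3 = 10, cell_type = NA_character_)
  expect_error(build_model_input(rec2), "c1", class = "perishell_model_error")
  empty <- build_model_input(rec[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("mean density is the deterministic transform of coefficient draws", {
  fit <- fake_fit(replicate(6, rep(log(0.00743), 50), simplify = FALSE))
  d <- mean_density(fit, "ChAT+/NOS-", "TH")
  expect_equal(d$median, 7.43, tolerance = 1e-12)
  expect_equal(d$ci_hi - d$ci_lo, 0)  # degenerate posterior: zero-width CI
})

test_that("density ratios transform coefficient differences draw-wise", {
  base <- rnorm(200, log(0.006), 0.05)
  fit <- fake_fit(list(base + log(2), base, base, base, base, base))
  r <- density_ratio(fit, "TH", "ChAT+/NOS-", "ChAT-/NOS+")
  expect_equal(r$median, 2, tolerance = 1e-12)
  expect_equal(r$ci_lo, 2, tolerance = 1e-12)
  expect_true(r$significant)
  same <- density_ratio(fit, "TH", "ChAT+/NOS-", "ChAT+/NOS-")
  expect_equal(c(same$median, same$ci_lo, same$ci_hi), c(1, 1, 1))
  ident <- fake_fit(replicate(6, base, simplify = FALSE))
  r2 <- density_ratio(ident, "ENK", "ChAT+/NOS-", "ChAT-/NOS+")
  expect_equal(c(r2$median, r2$ci_lo, r2$ci_hi), c(1, 1, 1))
  expect_error(density_ratio(fit, "TH", "ChAT+/NOS-", "nonsense"),
               class = "perishell_model_error")
})

test_that("the sampler is reproducible and validates its design", {
  rows <- simulate_rows(n_subjects = 4, cells = 10, seed = 3)
  f1 <- suppressWarnings(fit_nb_glmm(rows, chains = 2, warmup = 200, draws = 100,
                                     seed = 99))
  f2 <- suppressWarnings(fit_nb_glmm(rows, chains = 2, warmup = 200, draws = 100,
                                     seed = 99))
  expect_identical(f1$draws, f2$draws)
  expect_true(all(c("beta_pop[1]", "gam[1]", "sd_subj", "sd_gang") %in%
                    colnames(f1$draws)))
  expect_true(all(is.finite(f1$rhat)))
  expect_true(is.na(glance(f1)$divergences))

  td <- tidy(f1)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high", "rhat", "ess")
                  %in% names(td)))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))

  expect_error(fit_nb_glmm(rows[rows$subj == "S1", ], chains = 1,
                           warmup = 100, draws = 50),
               class = "perishell_model_error")
  # degenerate design: one combination entirely absent
  gone <- rows[!(rows$cell_type == "ChAT+/NOS+" & rows$marker == "ENK"), ]
  expect_error(fit_nb_glmm(gone, chains = 1, warmup = 100, draws = 50),
               class = "perishell_model_error")
})

test_that("posterior fixed effects agree with an independent ML fit", {
  skip_if_not_installed("glmmTMB")
  rows <- simulate_rows(seed = 21)
  fit <- suppressWarnings(
    fit_nb_glmm(rows, chains = 2, warmup = 600, draws = 600, seed = 5))
  rows$combo <- interaction(rows$cell_type, rows$marker, sep = " x ")
  ml <- glmmTMB::glmmTMB(
    count ~ 0 + combo + offset(log(volume)) + (1 | subj) + (1 | gang),
    family = glmmTMB::nbinom2, data = rows)
  ml_dens <- exp(unname(glmmTMB::fixef(ml)$cond)) * 1000
  post <- mean_densities(fit)
  key <- paste(post$cell_type, post$marker, sep = " x ")
  ml_ord <- ml_dens[match(key, sub("^combo", "", names(glmmTMB::fixef(ml)$cond)))]
  expect_equal(log(post$median), log(ml_ord), tolerance = 0.1)
})

test_that("Tukey contrasts recover a constructed group shift", {
  set.seed(33)
  delta <- 1500
  dat <- tibble::tibble(
    subject_id = rep(sprintf("S%d", 1:6), each = 8),
    ganglion_id = rep(rep(c("G1", "G2"), each = 4), 6),
    cell_type = rep(c("ChAT+/NOS-", "ChAT-/NOS+"), 24),
    volume_um3 = 3000 + delta * (rep(c("ChAT+/NOS-", "ChAT-/NOS+"), 24) == "ChAT+/NOS-") +
      rnorm(48, 0, 20))
  res <- morphometric_anova(dat, "volume_um3", unit_of_analysis = "ganglion_mean")
  expect_equal(res$unit_of_analysis, "ganglion_mean")
  pair <- res$tukey[grepl("ChAT\\-/NOS\\+", res$tukey$pair), ]
  expect_equal(abs(pair$diff), delta, tolerance = 0.02)
  expect_lt(res$anova$p_value, 1e-6)

  res2 <- morphometric_anova(dat, "volume_um3", unit_of_analysis = "cell")
  expect_equal(res2$anova$df1, 1)
  expect_equal(res2$anova$df2, 46)

  flat <- dplyr::mutate(dat, volume_um3 = 100)
  expect_error(morphometric_anova(flat, "volume_um3"),
               class = "perishell_model_error")
})

test_that("the ANOVA is calibrated under the null", {
  set.seed(44)
  ps <- replicate(10, {
    dat <- tibble::tibble(
      subject_id = rep(sprintf("S%d", 1:7), each = 8),
      ganglion_id = rep(rep(c("G1", "G2"), each = 4), 7),
      cell_type = sample(cell_types, 56, TRUE),
      volume_um3 = rlnorm(56, log(4000), 0.4))
    morphometric_anova(dat, "volume_um3")$anova$p_value
  })
  expect_gte(sum(ps > 0.05), 7)
})
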