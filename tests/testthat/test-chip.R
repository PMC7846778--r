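mk_pair <- function(chip_counts, input_counts, chip_total = NULL, input_total = NULL,
                    chip_spike = 1000, input_spike = 1000, id = "s") {
  regs <- sprintf("r%d", seq_along(chip_counts))
  chip <- chip_sample(id, "ChIP", setNames(chip_counts, regs),
                      target_total = chip_total %||% sum(chip_counts),
                      spikein_total = chip_spike)
  input <- chip_sample(paste0(id, "_in"), "input", setNames(input_counts, regs),
                       target_total = input_total %||% sum(input_counts),
                       spikein_total = input_spike)
  list(chip = chip, input = input)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("input normalisation applies the 0.5 offset and per-10M scaling", {
  p <- mk_pair(c(10, 0), c(4, 0), chip_total = 1e6, input_total = 1e6,
               chip_spike = 0, input_spike = 0)
  s <- normalised_signal(p$chip, p$input)
  expect_equal(unname(s[1]), 10.5 / 4.5)
  expect_equal(unname(s[2]), 1)        # offset keeps zero/zero finite at 1
  expect_true(all(s > 0))

  # doubling the ChIP total halves the value
  p2 <- mk_pair(c(10, 0), c(4, 0), chip_total = 2e6, input_total = 1e6,
                chip_spike = 0, input_spike = 0)
  s2 <- normalised_signal(p2$chip, p2$input)
  expect_equal(unname(s2[1]), unname(s[1]) / 2)

  # with no offset the value is invariant to scaling counts and totals together
  p3 <- mk_pair(c(20, 10), c(8, 2), chip_total = 1e6, input_total = 1e6,
                chip_spike = 0, input_spike = 0)
  p4 <- mk_pair(c(20, 10) * 3, c(8, 2), chip_total = 3e6, input_total = 1e6,
                chip_spike = 0, input_spike = 0)
  expect_equal(unclass(normalised_signal(p4$chip, p4$input, offset = 0)),
               unclass(normalised_signal(p3$chip, p3$input, offset = 0)))

  expect_error(normalised_signal(p$chip, mk_pair(1:3, 1:3)$input), "identical regions")
})

test_that("regions uncovered in every sample are dropped before analysis", {
  a <- mk_pair(c(5, 0, 0), c(2, 0, 1))
  regs <- covered_regions(list(a$chip, a$input))
  expect_setequal(regs, c("r1", "r3"))
  s <- normalised_signal(a$chip, a$input, regions = regs)
  expect_equal(names(s), c("r1", "r3"))
})

test_that("Rx scaling factors follow the input-corrected dRPTM formula", {
  # dRPTM: ChIP-n = 200, ChIP-ref = 100, IN-n = 100, IN-ref = 100 -> S_n = 2
  mk_run <- function(drptm, id, role) {
    # spike reads s with total 1e7 gives dRPTM = s
    chip_sample(id, role, counts = c(r1 = 100), target_total = 1e7 - drptm,
                spikein_total = drptm)
  }
  samples <- list(
    ref = list(chip = mk_run(100, "ref", "ChIP"), input = mk_run(100, "ref_in", "input")),
    n = list(chip = mk_run(200, "n", "ChIP"), input = mk_run(100, "n_in", "input")))
  rx <- rx_scaling_factor(samples, reference = "ref")
  expect_equal(rx$factor[rx$sample == "ref"], 1)     # exact identity
  expect_identical(rx$factor[rx$sample == "ref"], 1) # not just within tolerance
  expect_equal(rx$factor[rx$sample == "n"], 2)

  nospike <- samples
  nospike$n$input$spikein_total <- 0
  expect_error(rx_scaling_factor(nospike, "ref"), "spike-in")
  expect_error(rx_scaling_factor(samples, "missing"), "reference")
  nolist <- samples; nolist$n$input <- NULL
  expect_error(rx_scaling_factor(nolist, "ref"), "missing its ChIP or input")
})

test_that("applying Rx scaling rescales uniformly and replicate means commute", {
  p <- mk_pair(c(10, 20), c(5, 5))
  s <- normalised_signal(p$chip, p$input)
  rx <- data.frame(sample = c("s", "t"), drptm_chip = c(1, 2), drptm_input = c(1, 1),
                   factor = c(1, 2), stringsAsFactors = FALSE)
  attr(rx, "reference") <- "s"
  class(rx) <- c("rx_scaling", "data.frame")
  expect_equal(unclass(apply_rx_scaling(s, rx, "s")), unclass(s))  # S = 1 identity
  scaled <- apply_rx_scaling(s, rx, "t")
  expect_equal(unclass(scaled), unclass(s) / 2)  # uniform linear rescale by 1/S

  reps <- list(s, scaled)
  expect_equal(rx_replicate_mean(reps), (unclass(s) + unclass(scaled)) / 2)
})

test_that("a simulated global fold change is recovered through Rx scaling", {
  sim <- simulate_chip_experiment(chip_sim_config(
    n_cgis = 500, library_size = 1e6, global_fold_change = 2, seed = 5))
  rx <- rx_scaling_factor(sim$samples, reference = "ref")
  s_alt <- rx$factor[rx$sample == "alt"]
  expect_equal(s_alt, sim$truth$expected_scaling_factor, tolerance = 0.05)

  regs <- covered_regions(list(sim$samples$ref$chip, sim$samples$ref$input,
                               sim$samples$alt$chip, sim$samples$alt$input))
  sig_ref <- normalised_signal(sim$samples$ref$chip, sim$samples$ref$input, regions = regs)
  sig_alt <- apply_rx_scaling(
    normalised_signal(sim$samples$alt$chip, sim$samples$alt$input, regions = regs),
    rx, "alt")
  # per-region fold, aggregated over well-covered regions
  strong <- sim$samples$ref$chip$counts[regs] > 50
  fold <- median(unclass(sig_alt)[strong] / unclass(sig_ref)[strong])
  expect_equal(fold, 2, tolerance = 0.05)

  # symmetric samples: true factor 1
  sym <- simulate_chip_experiment(chip_sim_config(n_cgis = 500, library_size = 1e6,
                                                  global_fold_change = 1, seed = 6))
  rx_sym <- rx_scaling_factor(sym$samples, reference = "ref")
  expect_equal(rx_sym$factor[rx_sym$sample == "alt"], 1, tolerance = 0.05)
})

test_that("rank-group association splits evenly and reports CGI-level Spearman", {
  x <- c(20:1)  # 20 CGIs, descending so group 10 holds the largest signals
  da <- decile_association(x, x)
  expect_equal(as.integer(table(da$group)), rep(2L, 10))
  expect_equal(da$spearman_rho, 1)
  expect_equal(da$summary$median[10], 20 - 0.5)

  # remainder spread over the lowest groups
  da23 <- decile_association(seq_len(23), seq_len(23))
  expect_equal(as.integer(table(da23$group)), c(3L, 3L, 3L, rep(2L, 7)))

  # monotone but nonlinear response still gives rho = 1
  expect_equal(decile_association(1:50, (1:50)^3)$spearman_rho, 1)

  expect_error(decile_association(1:5, 1:5, n_groups = 10), "n_groups")
  expect_warning(decile_association(rep(1, 20), rnorm(20)), "ties")
})

test_that("decoupled signal and response stay inside permutation null bounds", {
  set.seed(skip_free_seed)
  n <- 1000
  sig <- rlnorm(n)
  resp <- rnorm(n)
  da <- decile_association(sig, resp)
  perm <- replicate(500, suppressWarnings(
    cor(sig, sample(resp), method = "spearman")))
  expect_lte(abs(da$spearman_rho), quantile(abs(perm), 0.99) + 0.01)
})

test_that("histone-mark linear model standardises predictors and flags fits", {
  set.seed(skip_free_seed)
  n <- 1000
  pred <- data.frame(h3k36me3 = rnorm(n), h3k4me3 = rnorm(n), h3k27me3 = rnorm(n))
  resp <- 2 * pred$h3k36me3 + rnorm(n, sd = 0.01)
  fit <- fit_histone_model(resp, pred)
  co <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  expect_equal(co$term[which.max(abs(co$estimate))], "h3k36me3")
  expect_gt(fit$r_squared, 0.99)

  # response independent of all predictors: coefficients near zero
  resp0 <- rnorm(n)
  fit0 <- fit_histone_model(resp0, pred)
  co0 <- fit0$coefficients[fit0$coefficients$term != "(Intercept)", ]
  expect_true(all(abs(co0$estimate) < 4 * co0$std_error))

  # single predictor, perfect fit
  fit1 <- suppressWarnings(fit_histone_model(2 + 3 * pred$h3k4me3, pred["h3k4me3"]))
  expect_equal(fit1$r_squared, 1)

  expect_error(fit_histone_model(resp, transform(pred, flat = 1)), "constant")
  dup <- pred; dup$copy <- dup$h3k36me3 + rnorm(n, sd = 1e-8)
  expect_true(fit_histone_model(resp, dup)$collinear)
})

test_that("qPCR percent input adjusts the input Ct to 100% at efficiency 2", {
  expect_equal(qpcr_percent_input(25, 25, 1), 100)
  expect_equal(qpcr_percent_input(22, 25, 0.01), 8)  # 100 * 2^3 * 0.01
  expect_lt(qpcr_percent_input(40, 25, 0.01), 1e-3)  # IP Ct -> infinity: -> 0
  expect_error(qpcr_percent_input(22, 25, 0), "input_fraction")
})

test_that("heatmap matrices cap display at the 90% quantile without truncating", {
  m <- matrix(1:100, nrow = 10, byrow = TRUE,
              dimnames = list(sprintf("cgi%02d", 1:10), NULL))
  hm <- heatmap_matrix(m, order_rows = FALSE)
  # order-statistic oracle: linear interpolation between sorted values
  v <- sort(as.numeric(m))
  h <- 0.9 * (length(v) - 1) + 1
  expect_equal(hm$display_max, v[floor(h)] + (h - floor(h)) * (v[floor(h) + 1] - v[floor(h)]))
  expect_equal(hm$display_min, 1)
  expect_equal(max(hm$matrix), 100)  # values not truncated

  expect_warning(hm0 <- heatmap_matrix(matrix(5, 3, 3)), "degenerate")
  expect_true(hm0$degenerate)

  # row ordering by mean is deterministic under ties (by region id)
  tied <- matrix(c(1, 3, 3, 1, 5, 6), nrow = 3, byrow = TRUE,
                 dimnames = list(c("b", "a", "c"), NULL))
  hm2 <- heatmap_matrix(tied)
  expect_equal(rownames(hm2$matrix), c("c", "a", "b"))
})
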