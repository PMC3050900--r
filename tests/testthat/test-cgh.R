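make_scan <- function(sample, reference, probe_id = NULL, step = "S1",
                      arm = "butanol") {
  if (is.null(probe_id)) probe_id <- sprintf("p%04d", seq_along(sample))
  sc <- data.frame(probe_id = probe_id, sample_intensity = sample,
                   reference_intensity = reference,
                   stringsAsFactors = FALSE)
  attr(sc, "step") <- step
  attr(sc, "arm") <- arm
  class(sc) <- c("array_scan", "data.frame")
  sc
}

test_that("LOWESS normalization is a no-op on unbiased data and removes
           smooth trends", {
  set.seed(1)
  a_true <- runif(1000, 6, 14)
  ref <- 2^a_true
  # M identically zero
  out0 <- lowess_normalize(make_scan(ref, ref))
  expect_equal(max(abs(out0$M)), 0, tolerance = 1e-12)

  # M = 0.5 + 0.1 * A exactly: local linear fit removes it everywhere
  m_lin <- 0.5 + 0.1 * a_true
  s <- ref * 2^m_lin
  # sample*ref product changes A; recompute so the injected trend is in the
  # realized A: choose channels symmetric around A
  samp <- 2^(a_true + m_lin / 2)
  refc <- 2^(a_true - m_lin / 2)
  out1 <- lowess_normalize(make_scan(samp, refc))
  inner <- out1$A > quantile(out1$A, 0.05) & out1$A < quantile(out1$A, 0.95)
  expect_lt(max(abs(out1$M[inner])), 1e-6)

  # a single spiked probe among nulls survives normalization
  m_sp <- rep(0, 1000); m_sp[500] <- 3
  out2 <- lowess_normalize(make_scan(2^(a_true + m_sp / 2),
                                     2^(a_true - m_sp / 2)))
  expect_gt(abs(out2$M[out2$probe_id == "p0500"]), 2.5)
  expect_lt(max(abs(out2$M[-500])), 0.2)
})

test_that("LOWESS removes the generator's cubic dye bias below 0.01 MAD", {
  set.seed(2)
  a_true <- runif(1000, 6, 14)
  x <- a_true - mean(a_true)
  bias <- 0.2 * x - 0.008 * x^2 + 0.003 * x^3
  out <- lowess_normalize(make_scan(2^(a_true + bias / 2),
                                    2^(a_true - bias / 2)))
  expect_lt(mean(abs(out$M)), 0.01)
})

test_that("non-positive intensities are dropped, with an error past 50%", {
  sc <- make_scan(c(100, 200, -5, 300), c(50, 0, 60, 70))
  out <- lowess_normalize(sc)
  expect_equal(attr(out, "n_dropped"), 2)
  expect_equal(nrow(out), 2)
  sc_bad <- make_scan(c(-1, -1, -1, 5), c(1, 1, 1, 5))
  expect_error(lowess_normalize(sc_bad), "50%")
})

test_that("gene profiles summarize probes by the median and log omissions", {
  mk_norm <- function(vals, probes, step, arm = "butanol") {
    out <- data.frame(probe_id = probes, A = 10, M = vals,
                      stringsAsFactors = FALSE)
    attr(out, "step") <- step; attr(out, "arm") <- arm
    out
  }
  sched <- data.frame(step = c("S1", "S2"))
  probes <- c("pA1", "pA2", "pA3", "pB1")
  pmap <- data.frame(probe_id = probes,
                     gene_id = c("gA", "gA", "gA", "gB"))
  norm <- list(mk_norm(c(1, 2, 9, 0.5), probes, "S1"),
               mk_norm(c(2, 2, 2, 0.7), probes, "S2"))
  prof <- gene_profiles(norm, pmap, sched)
  m <- prof$profiles$butanol
  expect_equal(m["gA", "S1"], 2)     # median of {1,2,9}
  expect_equal(m["gB", "S1"], 0.5)   # identity for a single probe
  expect_equal(m["gA", "S2"], 2)

  # unmapped probes are counted, unmapped genes absent from output
  pmap2 <- pmap[1:3, ]
  prof2 <- gene_profiles(norm, pmap2, sched)
  expect_false("gB" %in% rownames(prof2$profiles$butanol))
  expect_equal(prof2$n_unmapped_probes, 2)

  # a scan step outside the schedule is an error
  norm_bad <- list(mk_norm(1:4, probes, "S9"))
  expect_error(gene_profiles(norm_bad, pmap, sched), "S9")
  # a probe mapping to two genes is an error
  pmap_dup <- rbind(pmap, data.frame(probe_id = "pA1", gene_id = "gB"))
  expect_error(gene_profiles(norm, pmap_dup, sched), "more than one")
})

test_that("differential calling matches the closed-form t-test", {
  m <- rbind(strong = c(2.0, 2.1, 1.9, 2.0),
             weak = c(0.1, -0.1, 0.05, -0.05),
             null = c(0, 0, 0, 0),
             down = c(-1.0, -1.2, -0.9, -1.1))
  calls <- detect_differential(m, alpha = 0.05)
  strong <- calls[calls$gene_id == "strong", ]
  # t = 2.0 / (0.0816/2) ~ 49
  expect_equal(strong$p_value, t_p_oracle(m["strong", ]))
  expect_lt(strong$p_value, 1e-4)
  expect_identical(strong$direction, "enriched")
  expect_true(strong$significant)

  weak <- calls[calls$gene_id == "weak", ]
  expect_equal(weak$p_value, t_p_oracle(m["weak", ]))
  expect_gt(weak$p_value, 0.05)
  expect_false(weak$significant)

  nullrow <- calls[calls$gene_id == "null", ]
  expect_false(nullrow$significant)
  expect_true(nullrow$degenerate)

  down <- calls[calls$gene_id == "down", ]
  expect_identical(down$direction, "depleted")
  expect_true(down$significant)

  # zero variance with nonzero mean: p = 0, degenerate flag
  m2 <- rbind(const = c(1, 1, 1, 1), other = c(0, 0.1, -0.1, 0))
  calls2 <- detect_differential(m2)
  cr <- calls2[calls2$gene_id == "const", ]
  expect_equal(cr$p_value, 0)
  expect_true(cr$degenerate && cr$significant)

  expect_error(detect_differential(m[, 1, drop = FALSE]), ">= 2 steps")
})

test_that("type-I error of the one-sample call is near alpha under the null", {
  set.seed(7)
  m <- matrix(rnorm(2500 * 4, 0, 0.1), 2500, 4,
              dimnames = list(sprintf("g%04d", 1:2500), paste0("S", 1:4)))
  calls <- detect_differential(m, alpha = 0.05)
  expect_gt(mean(calls$significant), 0.03)
  expect_lt(mean(calls$significant), 0.07)
})

test_that("injected effects are recovered with matching direction", {
  set.seed(8)
  n <- 400
  eff <- sample(c(1, -1), n, replace = TRUE)
  m <- matrix(rnorm(n * 4, 0, 0.2), n, 4) + eff
  rownames(m) <- sprintf("g%03d", 1:n)
  calls <- detect_differential(m, alpha = 0.05)
  expect_gt(mean(calls$significant), 0.95)
  expect_identical(calls$direction,
                   unname(ifelse(rowMeans(m) > 0, "enriched", "depleted")))
  expect_true(all((calls$direction == "enriched") == (eff > 0)))
})

test_that("control-arm subtraction is a keyed set difference and idempotent", {
  mk_calls <- function(genes, dirs, sig = TRUE) {
    n <- length(genes)
    data.frame(gene_id = genes, direction = dirs,
               mean_log2 = rep(ifelse(dirs == "enriched", 1, -1),
                               length.out = n),
               p_value = rep(ifelse(sig, 0.01, 0.5), length.out = n),
               significant = rep(sig, length.out = n),
               degenerate = rep(FALSE, length.out = n),
               stringsAsFactors = FALSE)
  }
  but <- mk_calls(c("A", "B", "C"), rep("enriched", 3))
  ctl <- mk_calls("B", "enriched")
  out <- filter_control(but, ctl)
  expect_setequal(candidate_genes(out, "enriched"), c("A", "C"))

  # empty control leaves everything
  ctl0 <- mk_calls(character(), character())
  out0 <- filter_control(but, ctl0)
  expect_setequal(candidate_genes(out0, "enriched"), c("A", "B", "C"))

  # direction matters: a control-depleted gene does not mask enrichment
  ctl2 <- mk_calls("A", "depleted")
  out2 <- filter_control(but, ctl2)
  expect_true(out2$passed_control_filter[out2$gene_id == "A"])

  # non-significant control calls do not subtract
  ctl3 <- mk_calls("C", "enriched", sig = FALSE)
  out3 <- filter_control(but, ctl3)
  expect_true(all(out3$passed_control_filter))

  # idempotence and subset property
  twice <- filter_control(out, ctl)
  expect_identical(twice$passed_control_filter, out$passed_control_filter)
  expect_true(all(candidate_genes(out, "enriched") %in% but$gene_id))
})

test_that("normalization output is invariant to adding a smooth trend in A", {
  set.seed(9)
  a_true <- runif(800, 6, 14)
  m0 <- rnorm(800, 0, 0.15)
  base <- lowess_normalize(make_scan(2^(a_true + m0 / 2),
                                     2^(a_true - m0 / 2)))
  trend <- 0.3 * sin((a_true - 6) / 8 * pi) + 0.1 * (a_true - 10)
  shifted <- lowess_normalize(make_scan(2^(a_true + (m0 + trend) / 2),
                                        2^(a_true - (m0 + trend) / 2)))
  # same probes, nearly the same normalized values
  expect_lt(median(abs(shifted$M - base$M)), 0.05)
})
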