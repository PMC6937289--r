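test_that("probe filtering drops flagged probes and floors channels", {
  rep1 <- tibble::tibble(
    probe_id = paste0("p", 1:10),
    cy3 = c(0, 2:10), cy5 = c(10:2, 0.5),
    flag = c(rep("ok", 9), "bad")
  )
  f <- filter_features(rep1)
  expect_equal(nrow(f), 9)
  expect_equal(attr(f, "n_flagged"), 1)
  expect_true(all(f$cy3 >= 1) && all(f$cy5 >= 1))
  # floored zero gives a finite M downstream
  expect_true(all(is.finite(ma_transform(f)$M)))
  # all flags ok: identity on rows
  expect_equal(nrow(filter_features(dplyr::mutate(rep1, flag = "ok"))), 10)
  expect_error(filter_features(dplyr::mutate(rep1, flag = "bad")), "flagged")
  expect_error(filter_features(dplyr::mutate(rep1, cy3 = -1)), "non-negative")
})

test_that("MA transform is the standard log-ratio reparameterization", {
  m <- ma_transform(tibble::tibble(probe_id = c("a", "b", "c"),
                                   cy3 = c(100, 64, 256),
                                   cy5 = c(100, 256, 1024)))
  expect_equal(m$M, c(0, 2, 2))
  expect_equal(m$A[3], 9)
  expect_equal(m$A, 0.5 * log2(m$cy3 * m$cy5))
  expect_error(ma_transform(tibble::tibble(probe_id = "a", cy3 = 0, cy5 = 1)),
               "positive")
})

test_that("loess normalization removes smooth dye bias and keeps null data intact", {
  set.seed(42)
  # centred, trend-free data: fitted trend is essentially zero
  n <- 5000
  ma0 <- tibble::tibble(probe_id = paste0("p", 1:n),
                        A = runif(n, 6, 14), M = rnorm(n, 0, 0.2))
  norm0 <- loess_normalize(ma0)
  expect_lt(max(abs(norm0$dye_fit)), 0.02)

  # constant offset is absorbed entirely
  normc <- loess_normalize(dplyr::mutate(ma0, M = M + 0.7))
  expect_lt(max(abs(normc$M_norm - norm0$M_norm)), 0.02)

  # injected sinusoidal bias on 10,000 null probes: per-A-decile mean
  # residual below 0.05
  n <- 10000
  A <- runif(n, 6, 14)
  ma <- tibble::tibble(probe_id = paste0("p", 1:n), A = A,
                       M = 0.5 * sin(A / 2) + rnorm(n, 0, 0.2))
  normb <- loess_normalize(ma)
  dec <- cut(A, quantile(A, 0:10 / 10), include.lowest = TRUE)
  expect_lt(max(abs(tapply(normb$M_norm, dec, mean))), 0.05)

  expect_error(loess_normalize(ma0[1:20, ]), "at least 50")
  expect_error(loess_normalize(ma0, span = 1e-4), "window")
})

test_that("per-feature t-test matches hand-computed values and flags degeneracy", {
  norm <- tibble::tibble(
    replicate = rep(c("r1", "r2", "r3"), times = 3),
    probe_id = rep(c("up", "flat", "const"), each = 3),
    M_norm = c(0.8, 1.0, 1.2, 1, -1, 0, 0, 0, 0)
  )
  fs <- test_features(norm)
  up <- dplyr::filter(fs, probe_id == "up")
  expect_equal(up$mean_log2fc, 1.0)
  expect_equal(up$p_value, 0.0131, tolerance = 1e-2)
  expect_equal(up$p_value, 2 * pt(1 / (0.2 / sqrt(3)), 2, lower.tail = FALSE),
               tolerance = 1e-12)
  konst <- dplyr::filter(fs, probe_id == "const")
  expect_true(konst$degenerate)
  expect_true(is.na(konst$p_value))
  expect_equal(konst$mean_log2fc, 0)

  # symmetric two-replicate probe: mean 0, p 1
  fs2 <- test_features(tibble::tibble(
    replicate = c("r1", "r2"), probe_id = "s", M_norm = c(1, -1)
  ))
  expect_equal(fs2$mean_log2fc, 0)
  expect_equal(fs2$p_value, 1)
})

test_that("DEG calling applies the joint two-fold and p-value criterion", {
  fs <- tibble::tibble(
    probe_id = c("a", "b", "c", "d", "e"),
    n_rep = 3,
    mean_log2fc = c(1.0, 0.9, -2.44, 1.5, -1.2),
    p_value = c(0.013, 0.001, 0.001, 0.2, NA),
    degenerate = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  called <- call_degs(fs)
  expect_equal(called$call, c("up", "none", "down", "none", "none"))
  expect_equal(deg_counts(called)$n_total, 2)
  expect_error(call_degs(fs, lfc = -1), "positive")
})

test_that("DEG calls are invariant to probe order and channel rescaling", {
  sim <- gen_two_color_arrays(n_features = 3000, n_up = 30, n_down = 30,
                              flag_rate = 0, seed = 9)
  calls_of <- function(reps) {
    called <- call_degs(test_features(normalize_arrays(reps)))
    sort(called$probe_id[called$call != "none"])
  }
  base_calls <- calls_of(sim$replicates)
  shuffled <- lapply(sim$replicates, function(x) x[sample.int(nrow(x)), ])
  expect_equal(calls_of(shuffled), base_calls)
  rescaled <- lapply(sim$replicates, function(x)
    dplyr::mutate(x, cy3 = cy3 * 4, cy5 = cy5 * 4))
  expect_equal(calls_of(rescaled), base_calls)
})

test_that("null arrays give nominal raw p rates and essentially no joint calls", {
  sim <- gen_two_color_arrays(n_features = 20000, n_up = 0, n_down = 0,
                              noise_sd = 0.25, bias = NULL, flag_rate = 0,
                              seed = 77)
  fs <- test_features(normalize_arrays(sim$replicates))
  expect_equal(mean(fs$p_value <= 0.05, na.rm = TRUE), 0.05, tolerance = 0.3)
  expect_lt(abs(mean(fs$p_value <= 0.05, na.rm = TRUE) - 0.05), 0.015)
  called <- call_degs(fs)
  # joint two-fold + p criterion: under sd 0.25 the call rate is < 1e-4
  expect_lte(deg_counts(called)$n_total, 2)
})

test_that("GO enrichment equals exhaustive hypergeometric enumeration", {
  # worked example: N=20, K=5, n=5, k=4 -> 76/15504
  ann <- tibble::tibble(gene_id = paste0("g", 1:20),
                        term = rep(c("T1", "T2"), c(5, 15)))
  genes <- c(paste0("g", 1:4), "g20")  # 4 of 5 T1 members
  res <- go_enrichment(genes, ann)
  expect_equal(dplyr::filter(res, term == "T1")$p_value, 76 / 15504,
               tolerance = 1e-12)
  # total-inclusion minimum: k = n = K, p = 1/choose(N, K)
  ann2 <- tibble::tibble(gene_id = paste0("g", 1:20),
                         term = rep(c("T1", "T2"), c(3, 17)))
  res2 <- go_enrichment(paste0("g", 1:3), ann2)
  expect_equal(dplyr::filter(res2, term == "T1")$p_value, 1 / choose(20, 3),
               tolerance = 1e-12)
  # k = 0 is never enriched: p = 1 - P(overlap >= 1) complement, <= 1
  res0 <- dplyr::filter(res2, term == "T2")
  expect_lte(res0$p_value, 1)

  # property: agreement with explicit combinatorial sums on random
  # universes with N <= 25
  set.seed(7)
  for (i in 1:25) {
    N <- sample(5:25, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    genes_all <- paste0("G", seq_len(N))
    term_genes <- sample(genes_all, K)
    lst <- sample(genes_all, N)[seq_len(n)]
    k <- length(intersect(term_genes, lst))
    ann_i <- tibble::tibble(gene_id = term_genes, term = "T")
    p <- go_enrichment(lst, ann_i, universe = genes_all)$p_value
    expect_equal(p, hyper_tail_enum(N, K, n, k), tolerance = 1e-12)
  }
  expect_error(go_enrichment(character(0), ann), "non-empty")
  expect_error(go_enrichment("not_in_universe", ann), "not in the universe")
})

test_that("GO p-values are BH-adjusted and sorted", {
  uni <- gen_go_universe(n_genes = 300, n_terms = 12,
                         enriched_spec = list(term_size = 30, list_size = 15,
                                              overlap = 12), seed = 5)
  res <- go_enrichment(uni$gene_list, uni$annotation, uni$universe)
  expect_equal(res$p_adjust, p.adjust(res$p_value, "BH"))
  expect_equal(res$term[1], "GO:planted")
  expect_lt(res$p_value[1], 1e-4)
  expect_true(!is.unsorted(res$p_adjust))
})

test_that("qPCR concordance regression behaves like OLS on log2 ratios", {
  x <- c(-2.4, -1.5, -0.8, 0.1, 0.9, 1.7)
  d <- tibble::tibble(array_log2fc = x, qpcr_log2fc = x)
  fit <- suppressWarnings(qpcr_concordance(d))  # perfect-fit summary note
  expect_equal(fit$r.squared, 1)
  expect_equal(fit$slope, 1)
  d2 <- dplyr::mutate(d, qpcr_log2fc = 2 * array_log2fc)
  fit2 <- suppressWarnings(qpcr_concordance(d2))
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$r.squared, 1)
  g <- glance(fit2)
  expect_equal(g$nobs, 6)
  expect_error(qpcr_concordance(d[1:2, ]), "at least 3")
  expect_error(qpcr_concordance(dplyr::mutate(d, array_log2fc = 1)), "variance")

  # a 12-gene panel with qPCR noise sd 0.4 around y = x has expected
  # R^2 near 1/(1 + 0.16) ~ 0.86
  set.seed(99)
  r2 <- replicate(300, {
    xx <- rnorm(12, 0, 1)
    dd <- tibble::tibble(array_log2fc = xx,
                         qpcr_log2fc = xx + rnorm(12, 0, 0.4))
    qpcr_concordance(dd)$r.squared
  })
  expect_equal(mean(r2), 0.86, tolerance = 0.1 / 0.86)
  # delta-delta-Ct conversion: fold change 2^(-ddCt)
  expect_equal(ddct_to_log2fc(c(-2, 0, 1.5)), c(2, 0, -1.5))
})
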