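test_that("kappa on hand-computable contingency fixtures is exact", {
  # perfect agreement
  k <- cohens_kappa(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(k$kappa, 1, tolerance = 1e-12)
  # total systematic disagreement with balanced marginals
  k <- cohens_kappa(c("x", "x", "y", "y"), c("y", "y", "x", "x"))
  expect_equal(k$p_o, 0, tolerance = 1e-12)
  expect_equal(k$p_e, 0.5, tolerance = 1e-12)
  expect_equal(k$kappa, -1, tolerance = 1e-12)
  # confusion counts [[45, 5], [5, 45]]
  a <- rep(c("x", "x", "y", "y"), c(45, 5, 5, 45))
  b <- rep(c("x", "y", "x", "y"), c(45, 5, 5, 45))
  k <- cohens_kappa(a, b)
  expect_equal(k$p_o, 0.9, tolerance = 1e-12)
  expect_equal(k$p_e, 0.5, tolerance = 1e-12)
  expect_equal(k$kappa, 0.8, tolerance = 1e-12)
})

test_that("kappa matches an independent contingency-table computation on
           random label pairs", {
  set.seed(202)
  for (rep_i in 1:20) {
    cats <- letters[1:sample(2:5, 1)]
    n <- sample(10:80, 1)
    a <- sample(cats, n, replace = TRUE)
    b <- sample(cats, n, replace = TRUE)
    tab <- table(factor(a, cats), factor(b, cats))
    p_o <- sum(diag(tab)) / n
    p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
    oracle <- (p_o - p_e) / (1 - p_e)
    k <- cohens_kappa(a, b, cats)
    if (!k$undefined) expect_equal(k$kappa, oracle, tolerance = 1e-12)
    # symmetry and label-permutation invariance
    expect_equal(cohens_kappa(b, a, cats)$kappa, k$kappa,
                 tolerance = 1e-12)
    perm <- setNames(sample(cats), cats)
    expect_equal(cohens_kappa(unname(perm[a]), unname(perm[b]))$kappa,
                 k$kappa, tolerance = 1e-12)
  }
})

test_that("degenerate kappa inputs follow the documented contract", {
  k <- cohens_kappa(rep("a", 5), rep("a", 5))
  expect_equal(k$kappa, 1)
  expect_false(k$undefined)
  k <- cohens_kappa(rep("a", 4), c("a", "a", "a", "b"),
                    categories = c("a", "b"))
  expect_false(k$undefined)  # marginals differ, p_e < 1
  expect_error(cohens_kappa(c("a", "b"), c("a")), "same length")
  expect_error(cohens_kappa("a", "z", categories = c("a", "b")),
               "outside the category set")
})

test_that("event alignment pairs by id with a span fallback", {
  sim <- small_sim(seed = 21, n_documents = 3, events_per_doc = 4)
  corp <- sim$corpus
  al <- align_events(corp, corp)
  expect_identical(nrow(al$pairs), nrow(corp$events))
  expect_identical(nrow(al$unmatched_a), 0L)

  # permuted event ids still align through (trigger span, type)
  permuted <- corp
  permuted$events$event_id <- paste0("X", permuted$events$event_id)
  permuted$clues$event_id <- paste0("X", permuted$clues$event_id)
  permuted$participants$event_id <- paste0("X", permuted$participants$event_id)
  al <- align_events(corp, permuted)
  expect_identical(nrow(al$pairs), nrow(corp$events))
  expect_true(all(al$pairs$method == "span"))

  # an extra unmatched event in b is reported, not paired
  extra <- corp
  extra$events <- dplyr::bind_rows(
    extra$events,
    dplyr::mutate(extra$events[1, ], event_id = "E999",
                  trigger_start = NA_integer_, trigger_end = NA_integer_))
  al <- align_events(corp, extra)
  expect_identical(al$unmatched_b$event_id, "E999")

  other_docs <- corp
  other_docs$documents$doc_id <- paste0("z", other_docs$documents$doc_id)
  expect_error(align_events(corp, other_docs), "symmetric difference")
})

test_that("a corpus agrees perfectly with itself on all five dimensions", {
  sim <- small_sim(seed = 22, n_documents = 4, events_per_doc = 5)
  rep_ <- per_dimension_agreement(sim$corpus, sim$corpus)
  expect_identical(nrow(rep_$summary), 5L)
  expect_true(all(rep_$summary$kappa == 1))
  expect_identical(nrow(rep_$discrepancies), 0L)
  td <- generics::tidy(rep_)
  expect_identical(td, rep_$summary)
  gl <- generics::glance(rep_)
  expect_equal(gl$mean_kappa, 1)
  expect_identical(gl$n_discrepancies, 0L)
})

test_that("perturbing one dimension lowers only that dimension's kappa and
           fills the discrepancy report", {
  sim <- small_sim(seed = 23, n_documents = 40, events_per_doc = 10)
  eps <- 0.2
  flip <- matrix(c(1 - eps, eps, eps, 1 - eps), 2, byrow = TRUE,
                 dimnames = list(c("Positive", "Negative"),
                                 c("Positive", "Negative")))
  pert <- perturb_annotations(sim, list(Polarity = flip), seed = 24)
  rep_ <- per_dimension_agreement(sim$corpus, pert)
  s <- rep_$summary
  expect_true(s$kappa[s$dimension == "Polarity"] < 1)
  expect_true(all(s$kappa[s$dimension != "Polarity"] == 1))
  expect_true(all(rep_$discrepancies$dimension == "Polarity"))
  expect_identical(nrow(rep_$discrepancies),
                   sum(sim$corpus$events$polarity != pert$events$polarity))
})

test_that("estimated kappa converges to the closed-form value implied by
           the confusion matrix", {
  n_target <- 20000
  sim <- generate_corpus(
    mk_generation_spec(n_documents = 550, events_per_doc = n_target / 550),
    seed = 31)
  n <- nrow(sim$corpus$events)
  eps <- 0.05
  flip <- matrix(c(1 - eps, eps, eps, 1 - eps), 2, byrow = TRUE,
                 dimnames = list(c("Positive", "Negative"),
                                 c("Positive", "Negative")))
  pert <- perturb_annotations(sim, list(Polarity = flip), seed = 32)
  k <- per_dimension_agreement(sim$corpus, pert)$summary
  k <- k[k$dimension == "Polarity", ]

  # closed form from the generator's Negative share p and flip rate eps:
  # p_o = 1 - eps; marginal_b(Neg) = p(1-eps) + (1-p)eps
  p <- mean(sim$corpus$events$polarity == "Negative")
  p_o <- 1 - eps
  q <- p * (1 - eps) + (1 - p) * eps
  p_e <- p * q + (1 - p) * (1 - q)
  kappa_expected <- (p_o - p_e) / (1 - p_e)
  # 3 sigma of the binomial error in p_o, scaled through 1/(1 - p_e)
  tol <- 3 * sqrt(eps * (1 - eps) / n) / (1 - p_e)
  expect_equal(k$kappa, kappa_expected, tolerance = 2 * tol)
  expect_equal(k$p_o, p_o, tolerance = 3 * sqrt(eps * (1 - eps) / n) / p_o)
})
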