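make_fit <- function(model, q, item_params, class_dist, n = 100) {
  structure(list(model = model_spec(model), q = q,
                 item_params = item_params, class_dist = class_dist,
                 n_used = n, converged = TRUE),
            class = "cdm_fit")
}

one_item_q <- function() suppressWarnings(q_matrix(matrix(c(1, 0), 1)))

test_that("posterior class probabilities follow Bayes rule", {
  q <- one_item_q()
  fit <- make_fit("DINA", q, list(gs_params(0.2, 0.1)), rep(0.25, 4))
  post <- posterior_classes(response_data(matrix(1L, 1, 1)), fit)
  # normalize (0.2, 0.2, 0.9, 0.9) / 2.2 over classes (0,0),(0,1),(1,0),(1,1)
  expect_equal(unname(post[1L, ]), c(0.2, 0.2, 0.9, 0.9) / 2.2,
               tolerance = 1e-10)
  expect_equal(sum(post), 1)
})

test_that("a zero-information item returns the prior", {
  q <- one_item_q()
  prior <- c(0.4, 0.3, 0.2, 0.1)
  fit <- make_fit("DINA", q, list(gs_params(0.7, 0.3)), prior)  # g = 1 - s
  post <- posterior_classes(response_data(matrix(1L, 2, 1)), fit)
  expect_equal(unname(post[1L, ]), prior, tolerance = 1e-12)
})

test_that("deterministic parameters give a one-hot posterior", {
  q <- q_matrix(rbind(c(1, 0), c(0, 1)))
  fit <- make_fit("DINA", q, list(gs_params(0, 0), gs_params(0, 0)),
                  rep(0.25, 4))
  post <- posterior_classes(response_data(matrix(c(1L, 0L), 1)), fit)
  expect_equal(unname(post[1L, ]), c(0, 0, 1, 0))  # pattern (1,0)
})

test_that("EAP marginals sum posterior mass over mastering classes", {
  # one-hot posterior on (1,0,0,1)
  post <- matrix(0, 1, 16)
  post[1L, pattern_index(c(1, 0, 0, 1)) + 1L] <- 1
  expect_equal(unname(eap_mastery(post)[1L, ]), c(1, 0, 0, 1))

  unif <- matrix(1 / 16, 1, 16)
  expect_equal(unname(eap_mastery(unif)[1L, ]), rep(0.5, 4))

  post2 <- matrix(c(0.2, 0.2, 0.9, 0.9) / 2.2, 1)
  expect_equal(unname(eap_mastery(post2)[1L, ]), c(1.8 / 2.2, 0.5),
               tolerance = 1e-10)

  # oracle check on random posteriors: marginal = brute-force sum
  set.seed(14)
  for (rep_ in 1:5) {
    w <- matrix(rexp(3 * 16), 3)
    w <- w / rowSums(w)
    marg <- eap_mastery(w)
    pats <- attribute_patterns(4)
    for (a in 1:4) {
      expect_equal(marg[, a], rowSums(w[, pats[, a] == 1L]),
                   tolerance = 1e-12)
    }
  }
})

test_that("classification thresholds marginals with ties mastered", {
  expect_equal(classify_mastery(c(0.9, 0.2, 0.4, 0.6)), c(1L, 0L, 0L, 1L))
  expect_equal(classify_mastery(rep(0.5, 4)), rep(1L, 4))
  expect_equal(classify_mastery(c(0.49, 0.3, 0.1, 0.2)), rep(0L, 4))
})

test_that("classification is exact on noise-free data from an identifiable Q", {
  q <- identifiable_q()
  ip <- lapply(seq_len(nrow(q)), function(j) gs_params(0, 0))
  prof <- simulate_profiles(320, rep(1 / 16, 16), 4, seed = 31)
  resp <- simulate_responses(prof, q, "DINA", ip, seed = 32)
  fit <- make_fit("DINA", q, ip, rep(1 / 16, 16))
  for (m in c("EAP", "MAP", "MLE")) {
    got <- mastery_profiles(resp, fit, method = m)$pattern
    expect_equal(got, apply(prof, 1L, pattern_label))
  }
})

test_that("group attribute means average the marginals per group", {
  profiles <- data.frame(person_id = c("a", "b"), group = c("g", "g"),
                         prob_A1 = c(1, 0), prob_A2 = c(0, 0),
                         prob_A3 = c(0, 0), prob_A4 = c(0, 1))
  means <- group_attribute_means(profiles)
  expect_equal(unlist(means[1L, c("A1", "A2", "A3", "A4")]),
               c(A1 = 0.5, A2 = 0, A3 = 0, A4 = 0.5))

  single <- group_attribute_means(profiles[1L, ])
  expect_equal(single$A1, 1)

  # invariant to person ordering
  shuffled <- group_attribute_means(profiles[2:1, ])
  expect_equal(means, shuffled)
})

test_that("group means recover planted group-level mastery rates", {
  q <- pisa_q()
  ip <- init_item_params("LLM", q, p_null = 0.1, p_full = 0.9)
  k <- 4
  # group A: mostly full mastery; group B: mostly null
  dA <- c(rep(0.2 / 14, 14), 0, 0); dA[16] <- 0.8
  dB <- c(0.8, rep(0.2 / 15, 15))
  pA <- simulate_profiles(2000, dA / sum(dA), k, seed = 41)
  pB <- simulate_profiles(2000, dB / sum(dB), k, seed = 42)
  resp <- simulate_responses(rbind(pA, pB), q, "LLM", ip, seed = 43,
                             group = rep(c("A", "B"), each = 2000))
  fit <- em_fit(resp, q, "LLM", by_group = TRUE)
  prof <- mastery_profiles(resp, fit)
  means <- group_attribute_means(prof, digits = NA)
  truthA <- colMeans(pA)
  truthB <- colMeans(pB)
  expect_true(all(abs(unlist(means[means$group == "A", -(1:2)]) - truthA)
                  <= 0.03))
  expect_true(all(abs(unlist(means[means$group == "B", -(1:2)]) - truthB)
                  <= 0.03))
})

test_that("pattern frequency tables sort, restrict and tie-break", {
  profiles <- data.frame(
    person_id = as.character(1:10),
    group = "g",
    pattern = c(rep("(0,0,0,0)", 4), rep("(1,0,0,0)", 3),
                rep("(0,0,0,1)", 3)))
  freq <- pattern_frequencies(profiles)
  expect_equal(freq$pattern, c("(0,0,0,0)", "(0,0,0,1)", "(1,0,0,0)"))
  expect_equal(freq$proportion, c(0.4, 0.3, 0.3))  # tie: lower index first
  expect_equal(sum(freq$proportion), 1)

  top1 <- pattern_frequencies(profiles, top_k = 1)
  expect_equal(nrow(top1), 1L)
  expect_equal(top1$pattern, "(0,0,0,0)")

  all_same <- data.frame(person_id = "1", group = "g", pattern = "(0,0,0,0)")
  expect_equal(pattern_frequencies(all_same)$proportion, 1)
})
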