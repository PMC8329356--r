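# Shared fixtures: packaged published tables, tiny Q-matrices, and
# independent brute-force oracles the fast paths are checked against.

pisa_q <- function() {
  read_q_matrix(cdmtraj_example("pisa2012_q_matrix.csv"))
}

published_fit_table <- function() {
  read.csv(cdmtraj_example("pisa2012_model_fit.csv"), stringsAsFactors = FALSE)
}

published_top5 <- function() {
  read.csv(cdmtraj_example("pisa2012_top5_patterns.csv"),
           stringsAsFactors = FALSE)
}

published_score_counts <- function() {
  read.csv(cdmtraj_example("pisa2012_score_counts.csv"))
}

pisa_attributes <- function() {
  c("uncertainty", "average", "statistical_chart", "data_handling")
}

# Expand per-score counts into a response_data fixture: a person with t
# correct answers gets the first t items correct.
responses_from_counts <- function(counts, j) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    t_ <- counts$score[i]
    matrix(rep(c(rep(1L, t_), rep(0L, j - t_)), counts$frequency[i]),
           ncol = j, byrow = TRUE)
  })
  response_data(do.call(rbind, rows))
}

# One-item-per-attribute Q block prepended, making every pattern
# distinguishable from noise-free conjunctive responses.
identifiable_q <- function() {
  q_matrix(rbind(diag(4L), as.matrix(pisa_q())),
           item_ids = c(paste0("ident", 1:4), rownames(pisa_q())),
           attribute_names = colnames(pisa_q()))
}

# Plain-loop marginal log-likelihood: enumerate every class for every
# person, no matrix algebra shared with the implementation.
oracle_loglik <- function(scores, q, model, item_params, class_dist) {
  pats <- attribute_patterns(ncol(q))
  total <- 0
  for (i in seq_len(nrow(scores))) {
    person_lik <- 0
    for (c_ in seq_len(nrow(pats))) {
      lik <- class_dist[c_]
      for (j in seq_len(ncol(scores))) {
        x <- scores[i, j]
        if (is.na(x)) next
        p <- irf(model, item_params[[j]], q[j, ], pats[c_, ])
        lik <- lik * (if (x == 1) p else 1 - p)
      }
      person_lik <- person_lik + lik
    }
    total <- total + log(person_lik)
  }
  total
}

# Random small-but-valid CDM instance for property tests.
random_instance <- function(seed, n = 40, j_max = 3, k_max = 3) {
  set.seed(seed)
  k <- sample(2:k_max, 1)
  j <- sample(2:j_max, 1)
  repeat {
    qm <- matrix(rbinom(j * k, 1, 0.6), j, k)
    qm[rowSums(qm) == 0, sample.int(k, 1)] <- 1L
    if (all(colSums(qm) >= 1)) break
  }
  q <- q_matrix(qm)
  model <- sample(c("DINA", "DINO", "ACDM", "LLM", "RRUM", "GDINA"), 1)
  item_params <- random_item_params(model, q)
  dist <- as.numeric(rexp(2^k) + 0.05)
  dist <- dist / sum(dist)
  profiles <- simulate_profiles(n, dist, k, seed = seed + 1)
  responses <- simulate_responses(profiles, q, model, item_params,
                                  seed = seed + 2)
  list(q = q, model = model, item_params = item_params, class_dist = dist,
       responses = responses, profiles = profiles, k = k)
}

# Valid random parameters with non-negative main effects (monotone), so
# every model admits them.
random_item_params <- function(model, q) {
  spec <- model_spec(model)
  lapply(seq_len(nrow(q)), function(j) {
    kj <- sum(q[j, ])
    p0 <- runif(1, 0.05, 0.3)
    p1 <- runif(1, 0.7, 0.95)
    switch(spec$structure,
      conjunctive = ,
      disjunctive = gs_params(guess = p0, slip = 1 - p1),
      additive = {
        lk <- switch(spec$link, identity = identity, logit = qlogis,
                     log = log)
        additive_params(lk(p0), rep((lk(p1) - lk(p0)) / kj, kj))
      },
      saturated = {
        lv <- rowSums(attribute_patterns(kj))
        saturated_params(p0 + (p1 - p0) * lv / kj)
      })
  })
}
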