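table6_lattice <- function(country, ...) {
  t6 <- published_top5()
  build_lattice(4, t6[t6$country == country, ],
                attribute_names = pisa_attributes(), ...)
}

test_that("the knowledge-state lattice has the Boolean Hasse structure", {
  for (k in 1:4) {
    lat <- build_lattice(k)
    expect_equal(nrow(lat$nodes), 2^k)
    expect_equal(nrow(lat$edges), k * 2^(k - 1))
    # edges connect consecutive levels only
    lv <- setNames(lat$nodes$level, lat$nodes$pattern)
    expect_true(all(lv[lat$edges$to] - lv[lat$edges$from] == 1))
  }
  lat1 <- build_lattice(1)
  expect_equal(nrow(lat1$nodes), 2L)
  expect_equal(nrow(lat1$edges), 1L)
})

test_that("(1,0,0,1) has exactly its two one-attribute prerequisites", {
  lat <- build_lattice(4)
  preds <- lat$edges$from[lat$edges$to == "(1,0,0,1)"]
  expect_setequal(preds, c("(1,0,0,0)", "(0,0,0,1)"))
})

test_that("frequencies for patterns of the wrong length are rejected", {
  expect_error(build_lattice(4, c("(1,0,1)" = 0.5)), "length")
})

test_that("Argentina's published top-5 table yields the published chain", {
  lat <- table6_lattice("Argentina")
  tr <- extract_trajectory(lat, restrict_top_k = 5)
  expect_equal(tr$main, c("(0,0,0,0)", "(1,0,0,0)", "(1,0,0,1)",
                          "(1,0,1,1)", "(1,1,1,1)"))
  # first mastered: uncertainty; second: data handling
  expect_equal(tr$steps$attribute[1:2], c(1L, 4L))
})

test_that("Serbia keeps its level-1 secondary branch, the Emirates do not", {
  tr_rs <- extract_trajectory(table6_lattice("Serbia"), restrict_top_k = 5)
  expect_true(tr_rs$steps$secondary[1L])
  expect_equal(tr_rs$secondary$state[tr_rs$secondary$level == 1], "(0,0,0,1)")
  expect_equal(tr_rs$steps$ratio[1L], 0.075 / 0.073, tolerance = 1e-12)

  tr_ae <- extract_trajectory(table6_lattice("United Arab Emirates"),
                              restrict_top_k = 5)
  expect_false(tr_ae$steps$secondary[1L])
  expect_equal(tr_ae$steps$ratio[1L], 0.112 / 0.007, tolerance = 1e-12)

  # boundary: a ratio of exactly 10 still counts as a secondary trajectory
  lat <- build_lattice(2, c("(1,0)" = 0.10, "(0,1)" = 0.01))
  tr_edge <- extract_trajectory(lat)
  expect_true(tr_edge$steps$secondary[1L])
})

test_that("ten of the fourteen countries master uncertainty first", {
  trajs <- group_trajectories(
    transform(published_top5(), group = country),
    attribute_names = pisa_attributes(), restrict_top_k = 5)
  expect_length(trajs, 14L)
  cmp <- compare_trajectories(trajs)
  expect_equal(unname(cmp$step_counts["level1", "uncertainty"]), 10L)
  expect_equal(unname(cmp$step_counts["level1", "statistical_chart"]), 1L)
  first <- cmp$summary$step1_attribute
  expect_equal(sort(cmp$summary$group[first == "uncertainty"]),
               sort(c("United Arab Emirates", "Argentina", "Chile",
                      "Colombia", "Jordan", "Kazakhstan", "Mexico",
                      "Serbia", "Tunisia", "Uruguay")))
})

test_that("trajectory comparison clusters identical chains and drops empties", {
  t6 <- transform(published_top5(), group = country)
  trajs <- group_trajectories(t6, restrict_top_k = 5)
  two <- compare_trajectories(trajs[c("Argentina", "Uruguay")])
  expect_equal(two$clusters$size, 2)

  empty <- rbind(t6, data.frame(country = "Nowhere", rank = 1,
                                pattern = "(0,0,0,0)", proportion = 0,
                                group = "Nowhere"))
  expect_warning(group_trajectories(empty, restrict_top_k = 5), "Nowhere")
})

test_that("the main chain always spans null to full mastery", {
  for (seed in 1:10) {
    set.seed(seed)
    k <- sample(2:4, 1)
    freq <- setNames(runif(2^k), rownames(attribute_patterns(k)))
    tr <- extract_trajectory(build_lattice(k, freq))
    expect_length(tr$main, k + 1L)
    expect_equal(tr$main[1L], pattern_label(rep(0L, k)))
    expect_equal(tr$main[k + 1L], pattern_label(rep(1L, k)))
    bits <- lapply(tr$main, parse_pattern)
    for (l in seq_len(k)) {
      expect_equal(sum(abs(bits[[l + 1L]] - bits[[l]])), 1L)
      expect_true(all(bits[[l + 1L]] >= bits[[l]]))
    }
  }
})

test_that("extraction is invariant to frequency rescaling", {
  set.seed(99)
  freq <- setNames(runif(16), rownames(attribute_patterns(4)))
  tr1 <- extract_trajectory(build_lattice(4, freq))
  tr2 <- extract_trajectory(build_lattice(4, freq * 1000))
  expect_equal(tr1$main, tr2$main)
  expect_equal(tr1$steps$secondary, tr2$steps$secondary)
})

test_that("planted single chains are recovered for every attribute order", {
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1L, function(p) length(unique(p)) == 4L), ]
  expect_equal(nrow(perms), 24L)
  for (i in seq_len(nrow(perms))) {
    ord <- as.integer(perms[i, ])
    bits <- rep(0L, 4)
    chain <- pattern_label(bits)
    freq <- c("(0,0,0,0)" = 0.5)
    mass <- 0.3
    for (a in ord) {
      bits[a] <- 1L
      chain <- c(chain, pattern_label(bits))
      freq[pattern_label(bits)] <- mass
      mass <- mass * 0.7
    }
    lat <- build_lattice(4, freq)
    expect_equal(extract_trajectory(lat)$main, chain)
    # the greedy choice agrees with the global chain scorer on planted chains
    expect_equal(extract_trajectory(lat, scorer = "global")$main, chain)
  }
})

test_that("unsupported steps are resolved by tie-break and flagged", {
  lat <- build_lattice(3, c("(1,0,0)" = 0.4))
  tr <- extract_trajectory(lat)
  expect_equal(tr$main, c("(0,0,0)", "(1,0,0)", "(1,1,0)", "(1,1,1)"))
  expect_false(tr$steps$unsupported[1L])
  expect_true(all(tr$steps$unsupported[2:3]))
  expect_false(any(tr$steps$secondary))
})

test_that("DOT export distinguishes the main path and parses back", {
  lat2 <- build_lattice(2)
  dot <- export_graph(lat2, "DOT")
  expect_equal(length(grep("^  s[01]+ \\[", strsplit(dot, "\n")[[1L]])), 4L)
  expect_equal(length(grep("->", strsplit(dot, "\n")[[1L]])), 4L)

  tr <- extract_trajectory(table6_lattice("Argentina"), restrict_top_k = 5)
  tdot <- strsplit(export_graph(tr, "DOT"), "\n")[[1L]]
  solid <- grep("color=\"red\"", tdot, value = TRUE)
  pairs <- regmatches(solid, regexec("s([01]+) -> s([01]+)", solid))
  from <- vapply(pairs, `[[`, character(1L), 2L)
  to <- vapply(pairs, `[[`, character(1L), 3L)
  expect_length(from, 4L)
  # walk the solid red edges from the null state and compare to the chain
  chain <- "0000"
  while (chain[length(chain)] %in% from) {
    chain <- c(chain, to[match(chain[length(chain)], from)])
  }
  expect_equal(vapply(chain, function(s)
    pattern_label(as.integer(strsplit(s, "")[[1L]])), character(1L),
    USE.NAMES = FALSE), tr$main)

  expect_error(export_graph(tr, "PNG"))
})

test_that("trajectory JSON round-trips", {
  tr <- extract_trajectory(table6_lattice("Serbia"), restrict_top_k = 5)
  json <- export_graph(tr, "JSON")
  back <- trajectory_from_json(json)
  expect_equal(back$main, tr$main)
  expect_equal(back$secondary$state, tr$secondary$state)
  expect_equal(back$steps$ratio, tr$steps$ratio)
  expect_equal(unname(back$freq), unname(tr$freq))
})
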