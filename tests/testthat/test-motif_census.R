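test_that("named motifs classify to their field definitions", {
  # tri-trophic chain
  expect_equal(classify_triad(data.frame(from = c("A", "B"),
                                         to = c("B", "C"))), "s1")
  # omnivory: top consumer C feeds on both A and B
  expect_equal(classify_triad(data.frame(from = c("A", "B", "A"),
                                         to = c("B", "C", "C"))), "s2")
  # directed loop
  expect_equal(classify_triad(data.frame(from = c("A", "B", "C"),
                                         to = c("B", "C", "A"))), "s3")
  # apparent competition: two resources share consumer C
  expect_equal(classify_triad(data.frame(from = c("A", "B"),
                                         to = c("C", "C"))), "s4")
  # exploitative competition: resource A shared by two consumers
  expect_equal(classify_triad(data.frame(from = c("A", "A"),
                                         to = c("B", "C"))), "s5")
  expect_equal(classify_triad(data.frame(from = "A", to = "B"),
                              nodes = c("A", "B", "C")), "disconnected")
  expect_equal(classify_triad(data.frame(from = character(),
                                         to = character()),
                              nodes = c("A", "B", "C")), "disconnected")
  expect_error(classify_triad(data.frame(from = "A", to = "A"),
                              nodes = c("A", "B", "C")), "self-loop")
  expect_error(classify_triad(data.frame(from = "A", to = "B")), "three")
})

test_that("classification is invariant under node relabelling", {
  set.seed(21)
  for (r in 1:40) {
    code <- sample(0:63, 1)
    pairs <- list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
    sel <- which(bitwAnd(code, 2^(0:5)) > 0)
    ids <- c("A", "B", "C")
    e <- do.call(rbind, lapply(pairs[sel], function(p)
      data.frame(from = ids[p[1]], to = ids[p[2]],
                 stringsAsFactors = FALSE)))
    if (is.null(e)) e <- data.frame(from = character(), to = character())
    base <- classify_triad(e, nodes = ids)
    perm <- sample(ids)
    e2 <- e
    if (nrow(e2)) {
      e2$from <- perm[match(e2$from, ids)]
      e2$to <- perm[match(e2$to, ids)]
    }
    expect_equal(classify_triad(e2, nodes = perm), base)
  }
})

test_that("census counts match hand-derived small cases", {
  # 4-node chain: two tri-trophic triples, nothing else
  chain <- make_web(data.frame(from = c("A", "B", "C"),
                               to = c("B", "C", "D")))
  cc <- census(chain)
  expect_equal(unname(cc["s1"]), 2)
  expect_equal(sum(cc), 2)
  # in-star: every pair of leaves shares the hub
  star <- make_web(data.frame(from = c("B", "C", "D"), to = c("A", "A", "A")))
  cs <- census(star)
  expect_equal(unname(cs["s4"]), 3)
  expect_equal(sum(cs), 3)
  # empty web
  empty <- make_web(data.frame(from = character(), to = character()),
                    nodes = c("A", "B", "C"))
  expect_equal(sum(census(empty)), 0)
})

test_that("census equals brute force and conserves the triple count", {
  set.seed(8)
  for (r in 1:12) {
    n <- sample(6:15, 1)
    w <- random_web(n, runif(1, 0.1, 0.5))
    cc <- census(w)
    # brute force over all triples via classify_triad
    combos <- combn(w$nodes, 3)
    brute <- setNames(numeric(13), names(cc))
    disc <- 0
    for (k in seq_len(ncol(combos))) {
      trip <- combos[, k]
      e <- w$edges[w$edges$from %in% trip & w$edges$to %in% trip, ]
      cl <- classify_triad(e, nodes = trip)
      if (cl == "disconnected") disc <- disc + 1 else brute[cl] <- brute[cl] + 1
    }
    expect_equal(as.numeric(cc), unname(brute))
    expect_equal(sum(cc) + attr(cc, "disconnected"), choose(n, 3))
  }
})

test_that("census is invariant under node permutation", {
  set.seed(9)
  w <- random_web(12, 0.3)
  perm <- sample(w$nodes)
  w2 <- w
  w2$edges$from <- perm[match(w$edges$from, w$nodes)]
  w2$edges$to <- perm[match(w$edges$to, w$nodes)]
  w2$nodes <- sort(perm)
  expect_equal(as.numeric(census(w2)), as.numeric(census(w)))
})

test_that("census agrees with igraph's triad census", {
  set.seed(10)
  for (r in 1:10) {
    n <- sample(5:30, 1)
    w <- random_web(n, runif(1, 0.05, 0.4))
    g <- igraph::graph_from_data_frame(w$edges, directed = TRUE,
                                       vertices = w$nodes)
    tc <- igraph::triad_census(g)
    names(tc) <- c("003", "012", "102", "021D", "021U", "021C", "111D",
                   "111U", "030T", "030C", "201", "120D", "120U", "120C",
                   "210", "300")
    mp <- motif_classes()
    expect_equal(as.numeric(census(w)), unname(tc[mp$triad_type]))
  }
})

test_that("census_profile is deterministic and bounds free-floating counts", {
  comm <- tiny_community()
  pw <- build_probabilistic_web(comm, "plotA", "T1", scalar_config(50, 400))
  a <- census_profile(pw, iterations = 5, seed = 3)
  b <- census_profile(pw, iterations = 5, seed = 3)
  expect_identical(a, b)
  expect_true(all(a$per_iteration$free_floating <= a$per_iteration$full))
  gf <- a$grounded_fraction
  expect_true(all(gf[!is.na(gf)] >= 0 & gf[!is.na(gf)] <= 1))
  # deterministic probabilities: every iteration equals the single census
  pw1 <- build_probabilistic_web(comm, "plotA", "T1", scalar_config(1e9, 1e9))
  d <- census_profile(pw1, iterations = 3, seed = 1)
  one <- census(sample_binary_web(pw1, seed = 5))
  expect_equal(d$full, setNames(as.numeric(one), names(one)))
})
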