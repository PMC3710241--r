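test_that("semantic similarity handles the canonical cases", {
  h <- make_chain_hierarchy()
  expect_identical(semantic_similarity(h, "y", "y"), 1)
  # two children of the root share only the root (depth 0)
  expect_identical(semantic_similarity(h, "x", "z"), 0)
  # chain root -> x -> y: deepest common ancestor is x
  expect_equal(semantic_similarity(h, "x", "y"), 2 / 3)
  expect_error(semantic_similarity(h, "x", "nope"), "unknown term")
})

test_that("similarity is symmetric, in [0,1], and brute-force verified", {
  h <- random_hierarchy(25L, seed = 11L)
  m <- similarity_matrix(h)
  expect_true(all(m >= 0 & m <= 1))
  expect_identical(m, t(m))
  expect_identical(unname(diag(m)), rep(1, nrow(m)))

  # brute-force maximization over all common ancestors for a few pairs
  set.seed(1)
  for (k in 1:10) {
    ab <- sample(h$terms, 2L)
    common <- intersect(h$ancestors[[ab[1L]]], h$ancestors[[ab[2L]]])
    want <- if (!length(common)) 0 else {
      max(2 * h$depth[common] /
            (h$depth[[ab[1L]]] + h$depth[[ab[2L]]]))
    }
    expect_equal(semantic_similarity(h, ab[1L], ab[2L]), want)
  }
})

test_that("ward_cluster reproduces the Lance-Williams recurrence", {
  # 2 points: a single merge at the squared distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2L)
  hc <- ward_cluster(d2)
  expect_equal(unname(hc$height), 0.4^2)

  # 3 points: the tight pair merges first
  d3 <- matrix(c(0, 0.1, 1, 0.1, 0, 1, 1, 1, 0), 3L)
  hc3 <- ward_cluster(d3)
  expect_setequal(hc3$merge[1L, ], c(-1L, -2L))

  # 6 points: full independent Lance-Williams hand computation on
  # squared distances (Ward coefficients) must give the same merges
  set.seed(5)
  p <- matrix(runif(12L), ncol = 2L)
  d6 <- as.matrix(dist(p))
  hc6 <- ward_cluster(d6)

  lw_oracle <- function(d) {
    d <- d^2
    n <- nrow(d)
    active <- as.list(seq_len(n))
    sizes <- rep(1L, n)
    labels <- -seq_len(n)
    merges <- NULL
    heights <- numeric(0)
    diag(d) <- Inf
    for (step in seq_len(n - 1L)) {
      idx <- which(d == min(d), arr.ind = TRUE)[1L, ]
      i <- min(idx); j <- max(idx)
      merges <- rbind(merges, c(labels[i], labels[j]))
      heights <- c(heights, d[i, j])
      ni <- sizes[i]; nj <- sizes[j]
      for (k in seq_len(n)) {
        if (k %in% c(i, j) || is.na(sizes[k])) next
        nk <- sizes[k]
        d[i, k] <- d[k, i] <-
          ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] -
             nk * d[i, j]) / (ni + nj + nk)
      }
      sizes[i] <- ni + nj
      labels[i] <- step
      sizes[j] <- NA
      d[j, ] <- d[, j] <- Inf
    }
    list(merge = merges, height = heights)
  }
  oracle <- lw_oracle(d6)
  norm_merge <- function(m) t(apply(m, 1L, sort))
  expect_equal(norm_merge(hc6$merge), norm_merge(oracle$merge))
  expect_equal(unname(hc6$height), oracle$height)
  expect_true(all(diff(hc6$height) >= -1e-12))

  expect_error(ward_cluster(matrix(c(0, 1, 2, 0), 2L)), "symmetric")
})

test_that("the penalty-based cut selection finds planted group counts", {
  # two groups of 5 with uniform within-group distances
  d <- matrix(1, 10L, 10L)
  d[1:5, 1:5] <- 0.1
  d[6:10, 6:10] <- 0.1
  diag(d) <- 0
  expect_identical(as.integer(select_k(ward_cluster(d), d)), 2L)

  # three equidistant pairs
  d3 <- matrix(1, 6L, 6L)
  for (g in list(1:2, 3:4, 5:6)) d3[g, g] <- 0.1
  diag(d3) <- 0
  expect_identical(as.integer(select_k(ward_cluster(d3), d3)), 3L)

  expect_error(select_k(ward_cluster(d[1:2, 1:2]), d[1:2, 1:2]),
               "at least 3")
})

test_that("select_k equals an exhaustive per-level penalty scan", {
  set.seed(9)
  p <- matrix(runif(24L), ncol = 2L)
  d <- as.matrix(dist(p))
  hc <- ward_cluster(d)
  k <- select_k(hc, d)

  n <- nrow(d)
  ks <- 2:(n - 1L)
  spread <- vapply(ks, function(kk) {
    cl <- cutree(hc, k = kk)
    per <- vapply(split(seq_len(n), cl), function(idx) {
      if (length(idx) < 2L) return(NA_real_)
      sub <- d[idx, idx]
      mean(sub[upper.tri(sub)])
    }, 0)
    mean(per, na.rm = TRUE)
  }, 0)
  norm <- 1 + (n - 3) * (spread - min(spread)) / diff(range(spread))
  pen <- norm + ks
  expect_identical(as.integer(k), as.integer(ks[which.min(pen)]))
})

test_that("term clusters partition the input and are named by medoid", {
  h <- make_two_subtree_hierarchy()
  terms <- c("l1", "l2", "l3", "r1", "r2", "r3")
  tc <- build_term_clusters(terms, h, k = 2L)
  expect_identical(tc$k, 2L)
  mem <- lapply(tc$clusters, `[[`, "members")
  expect_setequal(unlist(mem), terms)
  # the two clusters are exactly the two subtrees
  expect_true(setequal(mem[[1L]], c("l1", "l2", "l3")) ||
                setequal(mem[[1L]], c("r1", "r2", "r3")))
  expect_length(intersect(mem[[1L]], mem[[2L]]), 0L)
  for (cl in tc$clusters) {
    expect_true(cl$representative %in% cl$members)
    expect_match(cl$name, paste0("^", cl$index, "_"))
  }

  # k override = n: every term its own cluster and its own representative
  tc_n <- build_term_clusters(terms, h, k = length(terms))
  expect_identical(tc_sizes(tc_n), rep(1L, length(terms)))
  expect_setequal(vapply(tc_n$clusters, `[[`, "", "representative"),
                  terms)
  expect_error(build_term_clusters(terms, h, k = 10L), "between 1")
})

test_that("clustering is deterministic and always a partition", {
  h <- random_hierarchy(30L, seed = 21L)
  tc1 <- build_term_clusters(h$terms, h)
  tc2 <- build_term_clusters(h$terms, h)
  expect_identical(tc1, tc2)

  for (seed in c(31L, 32L, 33L)) {
    hh <- random_hierarchy(18L, seed = seed)
    tc <- build_term_clusters(hh$terms, hh)
    mem <- lapply(tc$clusters, `[[`, "members")
    expect_setequal(unlist(mem), hh$terms)
    expect_identical(sum(lengths(mem)), length(hh$terms))
  }
})
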