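test_that("top-k candidates are the strongest cells with index tie-breaks", {
  expect_equal(topk_candidates(c(.1, .5, .3, .2), 2), c(2L, 3L))
  expect_equal(sort(topk_candidates(rnorm(9), 9)), 1:9)
  expect_equal(topk_candidates(rep(1, 6), 3), 1:3)
  expect_error(topk_candidates(rnorm(4), 5), "1..4")
})

# Build a circuit whose top prediction after word w is always next_of[w]:
# identity output map plus a strong feedforward column pattern.
oracle_circuit <- function(n, next_of) {
  cc <- build_circuit(n, n_purkinje = n, seed = 1)
  cc$W_ff <- matrix(0, n, n)
  for (w in seq_len(n)) cc$W_ff[next_of[w], w] <- 10
  cc$W_rec <- matrix(0, n, n)
  cc$b_p <- numeric(n)
  cc$W_out <- diag(n)
  cc$b_out <- numeric(n)
  cc
}

label_corpus <- function(code_rows, roles = NULL, types = NULL) {
  n <- lengths(code_rows)
  cann:::new_corpus(tibble::tibble(
    sentence = rep(seq_along(code_rows), n),
    position = unlist(lapply(n, seq_len)),
    token = as.character(unlist(code_rows)),
    role = if (is.null(roles)) "unlabeled" else unlist(roles),
    type = if (is.null(types)) "other" else unlist(types),
    code = as.integer(unlist(code_rows))))
}

test_that("the correct rate counts top-k hits and excludes UNK targets", {
  # cyclic successor: a perfect predictor scores 100%
  nxt <- c(2L, 3L, 4L, 1L)
  cc <- oracle_circuit(4, nxt)
  corpus <- label_corpus(list(c(1L, 2L, 3L), c(3L, 4L, 1L)))
  expect_equal(correct_rate(cc, corpus, k = 1), 100)
  # an anti-oracle with k = 1 scores 0
  expect_equal(correct_rate(oracle_circuit(4, c(3L, 4L, 1L, 2L)), corpus,
                            k = 1), 0)
  # 3 eligible positions, 2 hits -> 66.7%
  mixed <- label_corpus(list(c(1L, 2L, 3L, 1L)))  # targets 2, 3, 1
  half <- oracle_circuit(4, c(2L, 3L, 3L, 1L))    # wrong only after word 3
  expect_equal(correct_rate(half, mixed, k = 1), 100 * 2 / 3,
               tolerance = 1e-12)
  # positions whose target is the UNK cell (here cell 4) are excluded:
  # only the word-4 -> 2 transition is scored
  unkish <- label_corpus(list(c(1L, 4L, 2L, 4L)))  # targets 4, 2, 4
  expect_equal(correct_rate(oracle_circuit(4, nxt), unkish, k = 1), 0)
  expect_equal(correct_rate(oracle_circuit(4, c(3L, 3L, 3L, 2L)), unkish,
                            k = 1), 100)
  expect_error(correct_rate(cc, label_corpus(list(c(1L, 4L)))),
               "No eligible")
})

test_that("word-type and role conditions restrict the scored positions", {
  types <- list(c("other", "verb", "noun", "other"))
  roles <- list(c("S", "V", "O", "other"))
  corpus <- label_corpus(list(c(1L, 2L, 3L, 1L)), roles, types)
  full <- oracle_circuit(4, c(2L, 3L, 1L, 1L))   # correct at targets 2 and 3
  expect_equal(correct_rate(full, corpus, k = 1,
                            prev_type = "verb", target_type = "noun"), 100)
  miss <- oracle_circuit(4, c(2L, 4L, 1L, 1L))   # wrong after the verb
  expect_equal(correct_rate(miss, corpus, k = 1,
                            prev_type = "verb", target_type = "noun"), 0)
  expect_equal(correct_rate(full, corpus, k = 1, target_role = "O"), 100)
  expect_error(correct_rate(full, corpus, prev_type = "be-verb"),
               "No eligible")
})

test_that("activity matrices align activities with labels for each layer", {
  tf <- trained_fixture()
  am <- activity_matrix(tf$fit, tf$evalc, layer = "purkinje")
  expect_equal(nrow(am$values), nrow(tf$evalc))
  expect_equal(ncol(am$values), 48)
  expect_equal(am$labels$role, tf$evalc$role)
  ai <- activity_matrix(tf$fit, tf$evalc, layer = "input")
  expect_true(all(rowSums(ai$values) == 1))
  expect_equal(apply(ai$values, 1, which.max), tf$evalc$code)
  # blocked circuits give duplicate rows for duplicate words
  bl <- block_recurrent(tf$fit$circuit)
  ab <- activity_matrix(bl, tf$evalc, layer = "purkinje")
  by_word <- split(as.data.frame(ab$values), ab$labels$code)
  for (rows in by_word) {
    expect_true(all(duplicated(rows)[-1]))
  }
})

test_that("PCA projections preserve variance structure", {
  # 2-D data linearly embedded in 40 cells: two components explain ~100%
  set.seed(3)
  z <- matrix(rnorm(400), 200, 2)
  basis <- qr.Q(qr(matrix(rnorm(80), 40, 2)))
  am <- as_activity(z %*% t(basis), sample(c("S", "V"), 200, TRUE))
  pca <- pca_project(am, 2)
  expect_gte(sum(pca$explained_variance[1:2]), 0.999)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  expect_equal(unname(crossprod(pca$rotation)), diag(40), tolerance = 1e-8)
  expect_error(pca_project(as_activity(matrix(0, 10, 4),
                                       rep("S", 10)), 2),
               "zero variance")
})

test_that("separable clusters reach 100% and unit-direction recovery works", {
  set.seed(4)
  n <- 120
  x <- matrix(rnorm(n * 10, sd = 0.1), n, 10)
  roles <- rep(c("S", "V"), each = n / 2)
  x[roles == "S", 7] <- x[roles == "S", 7] + 8   # separation along cell 7
  am <- as_activity(x, roles)
  rep <- svm_separation(am, contrast = "S", n_repeats = 16, seed = 2)
  expect_equal(rep$mean_accuracy, 100)
  w <- linear_separating_direction(am, "S")
  expect_equal(sqrt(sum(w^2)), 1, tolerance = 1e-9)
  expect_gt(abs(w[7]), 0.99)
  expect_gt(w[7], 0)  # the S side is positive along cell 7
})

test_that("similarity indices are squared projections summing to one", {
  basis <- qr.Q(qr(matrix(rnorm(400), 20, 20)))
  si <- similarity_index(basis[, 1], basis)
  expect_equal(si$similarity[1], 1, tolerance = 1e-12)
  expect_equal(sum(si$similarity[-1]), 0, tolerance = 1e-12)
  mid <- (basis[, 1] + basis[, 2]) / sqrt(2)
  si45 <- similarity_index(mid, basis)
  expect_equal(si45$similarity[1:2], c(0.5, 0.5), tolerance = 1e-12)
  for (i in 1:100) {
    v <- rnorm(20); v <- v / sqrt(sum(v^2))
    expect_lt(abs(sum(similarity_index(v, basis)$similarity) - 1), 1e-9)
  }
  expect_error(similarity_index(rnorm(20), basis), "unit norm")
})

test_that("separating directions and PCA axes agree for trained circuits", {
  tf <- trained_fixture()
  am <- activity_matrix(tf$fit, tf$evalc, layer = "purkinje")
  pca <- pca_project(am, 3)
  w <- linear_separating_direction(am, "V")
  si <- similarity_index(w, pca$rotation)
  expect_equal(sum(si$similarity), 1, tolerance = 1e-9)
  expect_true(all(si$similarity >= 0 & si$similarity <= 1))
})

test_that("weight statistics summarize sign structure and silent synapses", {
  cc <- build_circuit(60, n_purkinje = 30, seed = 6)
  ws <- weight_distribution_stats(cc)
  expect_equal(ws$summary$frac_positive, 0.5, tolerance = 0.05)
  expect_equal(ws$summary$n, 1800)
  expect_equal(sum(ws$histogram$count), 1800)

  ws <- weight_study_fixture()
  wse <- weight_distribution_stats(ws$ei)
  expect_equal(wse$summary$population, c("excitatory", "inhibitory"))
  exc <- wse$summary[wse$summary$population == "excitatory", ]
  expect_equal(exc$frac_negative, 0)
  # the excitatory-limited population accumulates silent synapses; the
  # positive part of the unconstrained circuit shows no such peak
  w_plain <- ws$plain$circuit$W_ff
  tau_plain <- 0.02 * stats::sd(w_plain)
  silent_pos_plain <- mean(w_plain[w_plain > 0] < tau_plain)
  expect_gt(exc$frac_silent, 2 * silent_pos_plain)
})
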