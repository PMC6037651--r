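test_that("character resampling is uniform-with-replacement and seeded", {
  cm <- sitophilus_matrix()
  r1 <- resample_matrix(cm, seed = 7)
  r2 <- resample_matrix(cm, seed = 7)
  expect_identical(r1$states, r2$states)
  expect_identical(r1$ordered, r2$ordered)
  expect_identical(dim(r1), dim(cm))
  expect_identical(rownames(r1$states), rownames(cm$states))

  # one character: the only possible draw is that character
  one <- char_matrix(cm$states[, 1, drop = FALSE], ordered = cm$ordered[1])
  expect_identical(resample_matrix(one, seed = 1)$states[, 1],
                   one$states[, 1])

  # ordered flags travel with the drawn characters
  drawn <- sub("\\.\\d+$", "", colnames(r1$states))
  expect_identical(r1$ordered, unname(cm$ordered[match(drawn,
                                                       colnames(cm$states))]))
})

test_that("a unanimous matrix yields 100% support for its split", {
  m <- matrix(rep(c(0L, 0L, 1L, 1L, 0L), 6), nrow = 5,
              dimnames = list(c("a", "b", "c", "d", "e"), paste0("k", 1:6)))
  bs <- bootstrap_support(char_matrix(m), replicates = 500, seed = 1)
  expect_identical(split_support(bs, c("c", "d")), 100)
  expect_true(all(bs$support >= 0 & bs$support <= 100))
})

test_that("single-informative-character support matches the closed form", {
  # one {c,d}-supporting character among 20, the rest constant: a replicate
  # resolves {c,d} iff the character is drawn at least once,
  # P = 1 - (19/20)^20 ~ 64.15%
  m <- cbind(matrix(0L, 5, 19), c(0L, 0L, 1L, 1L, 0L))
  dimnames(m) <- list(c("a", "b", "c", "d", "e"), paste0("k", 1:20))
  B <- 20000
  bs <- bootstrap_support(char_matrix(m), replicates = B, seed = 2)
  p <- 1 - (19 / 20)^20
  mc_se <- sqrt(p * (1 - p) / B)
  got <- split_support(bs, c("c", "d"))
  expect_lt(abs(got / 100 - p), 3 * mc_se)
})

test_that("support estimates are reproducible and converge with replicates", {
  cm <- sitophilus_matrix()
  zo <- c("Sitophilus_zeamais", "Sitophilus_oryzae")
  b1 <- bootstrap_support(cm, replicates = 4000, seed = 3)
  b1b <- bootstrap_support(cm, replicates = 4000, seed = 3)
  expect_identical(b1$support, b1b$support)

  b2 <- bootstrap_support(cm, replicates = 16000, seed = 3)
  # Monte-Carlo convergence: estimates at two replicate counts are within a
  # few combined standard errors of each other
  p <- split_support(b2, zo) / 100
  se <- 100 * sqrt(p * (1 - p)) * sqrt(1 / 4000 + 1 / 16000)
  expect_lt(abs(split_support(b1, zo) - split_support(b2, zo)), 4 * se)
})

test_that("fractional tie handling never reports less support than strict", {
  cm <- sitophilus_matrix()
  st <- bootstrap_support(cm, replicates = 3000, seed = 4, tie_rule = "strict")
  fr <- bootstrap_support(cm, replicates = 3000, seed = 4,
                          tie_rule = "fractional")
  expect_identical(st$masks, fr$masks)
  expect_true(all(fr$support - st$support >= -1e-9))
})

test_that("annotation labels nodes and collapses weak ones", {
  m <- matrix(rep(c(0L, 0L, 1L, 1L, 0L), 6), nrow = 5,
              dimnames = list(c("a", "b", "c", "d", "e"), paste0("k", 1:6)))
  cm <- char_matrix(m, outgroup = "e")
  bs <- bootstrap_support(cm, replicates = 500, seed = 1)
  tr <- root_with_outgroup(
    ape::read.tree(text = "((a,b),(c,d),e);"), "e")

  ann <- annotate_and_collapse(tr, bs, threshold = 50)
  labs <- ann$node.label[nzchar(ann$node.label)]
  expect_true("100" %in% labs)
  # the unsupported {a,b} node is gone
  parts <- ape::prop.part(ann)
  clades <- lapply(parts, function(i) sort(attr(parts, "labels")[i]))
  expect_false(any(vapply(clades, identical, TRUE, y = c("a", "b"))))
  expect_true(any(vapply(clades, identical, TRUE, y = c("c", "d"))))

  # threshold 100 collapses everything into the root polytomy
  flat <- annotate_and_collapse(tr, bs, threshold = 100)
  expect_lte(flat$Nnode, 2L)
})

test_that("bootstrap errors on degenerate requests", {
  cm <- sitophilus_matrix()
  expect_error(bootstrap_support(cm, replicates = 0), ">= 1")
  tiny <- char_matrix(cm$states[1:3, ], ordered = cm$ordered)
  expect_error(bootstrap_support(tiny, replicates = 10), ">= 4 taxa")
})
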