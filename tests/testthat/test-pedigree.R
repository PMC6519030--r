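test_that("pedigree validation catches structural errors", {
  ok <- data.frame(id = c("a", "b", "c"), dam = c(NA, NA, "a"),
                   sire = c(NA, NA, "b"))
  expect_silent(validate_pedigree(ok))
  expect_error(validate_pedigree(rbind(ok, ok[1, ])), "duplicate")
  bad_parent <- data.frame(id = "a", dam = "ghost", sire = NA)
  expect_error(validate_pedigree(bad_parent), "not present")
  self <- data.frame(id = "a", dam = "a", sire = NA)
  expect_error(validate_pedigree(self), "cycle")
  cyc <- data.frame(id = c("a", "b"), dam = c("b", "a"), sire = c(NA, NA))
  expect_error(validate_pedigree(cyc), "cycle")
  bad_cohort <- data.frame(id = c("a", "b"), dam = c(NA, "a"),
                           sire = c(NA, NA), cohort = c(5, 3))
  expect_error(validate_pedigree(bad_cohort), "cohort")
})

test_that("relationship matrix reproduces textbook kinship values", {
  # two unrelated founders
  f2 <- data.frame(id = c("a", "b"), dam = c(NA, NA), sire = c(NA, NA))
  expect_equal(amatrix(f2), diag(2), ignore_attr = TRUE)
  # parent-offspring 0.5, full sibs 0.5, half sibs 0.25
  ped <- data.frame(id = c("d", "s", "s2", "o1", "o2", "h"),
                    dam = c(NA, NA, NA, "d", "d", "d"),
                    sire = c(NA, NA, NA, "s", "s", "s2"))
  A <- amatrix(ped)
  expect_equal(A["d", "o1"], 0.5)
  expect_equal(A["o1", "o2"], 0.5)
  expect_equal(A["o1", "h"], 0.25)
  expect_equal(unname(diag(A)), rep(1, 6))
  # offspring of full sibs is inbred: F = 0.25
  inb <- rbind(ped, data.frame(id = "z", dam = "o1", sire = "o2"))
  rel <- build_relationship_inverse(inb)
  expect_equal(unname(rel$F["z"]), 0.25)
  expect_equal(amatrix(inb)["z", "z"], 1.25)
})

test_that("sparse A-inverse matches the dense tabular inverse", {
  for (seed in 1:3) {
    ped <- random_pedigree(n = 50, seed = seed)
    A <- amatrix(ped)
    rel <- build_relationship_inverse(ped)
    expect_lt(max(abs(as.matrix(rel$Ainv %*% A) - diag(nrow(ped)))), 1e-8)
    # inbreeding from the traversal equals the tabular diagonal
    expect_equal(unname(rel$F), unname(diag(A)) - 1, tolerance = 1e-12)
  }
})

test_that("the non-inbred approximation drops inbreeding corrections", {
  ped <- random_pedigree(n = 40, seed = 4)
  rel <- build_relationship_inverse(ped, inbreeding = FALSE)
  expect_equal(unname(rel$F), rep(0, nrow(ped)))
})

test_that("pedigree permutation keeps shape but rewires parentage", {
  d <- small_dataset()
  set.seed(8)
  perm <- permute_pedigree(d$pedigree)
  expect_equal(dim(perm), dim(d$pedigree))
  expect_equal(perm$id, d$pedigree$id)
  expect_silent(validate_pedigree(perm))
  nonf <- !is.na(d$pedigree$dam)
  expect_gt(mean(perm$dam[nonf] != d$pedigree$dam[nonf]), 0.5)
})
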