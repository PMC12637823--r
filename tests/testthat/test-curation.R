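# Curation rules: entity filtering, dedup, time split, optimal chain
# mapping, redundancy filtering, and size filters.

test_that("assemblies with non-polypeptide chains are removed", {
  recs <- rbind(
    assembly_rows("asm1", "2020-01-01", c("MKV", "AAC"), c(2L, 2L)),
    assembly_rows("asm2", "2020-01-02", c("MKV", "ACGU"), c(1L, 1L),
                  polymer = c("polypeptide(L)", "polyribonucleotide")),
    assembly_rows("asm3", "2020-01-03", "MMM", 3L)
  )
  kept <- filter_polypeptide(recs)
  expect_setequal(unique(kept$assembly_id), c("asm1", "asm3"))
  empty <- recs[0, ]
  expect_equal(nrow(filter_polypeptide(empty)), 0L)
})

test_that("composition dedup keeps one earliest representative", {
  recs <- rbind(
    assembly_rows("late", "2021-06-01", c("MKV", "AAC"), c(2L, 2L)),
    assembly_rows("early", "2020-01-01", c("AAC", "MKV"), c(2L, 2L)),
    assembly_rows("diffstoich", "2020-02-01", c("MKV", "AAC"), c(1L, 1L)),
    assembly_rows("diffseq", "2020-03-01", c("MKV", "CCC"), c(2L, 2L))
  )
  kept <- dedupe_compositions(recs)
  ids <- unique(kept$assembly_id)
  expect_true("early" %in% ids)       # earliest date wins
  expect_false("late" %in% ids)
  expect_true(all(c("diffstoich", "diffseq") %in% ids))
})

test_that("time split partitions by date and gates test on support", {
  recs <- rbind(
    assembly_rows("tr", "2023-09-30", "MKV", 2L),
    assembly_rows("va", "2024-03-01", "MKV", 2L),
    assembly_rows("te", "2024-08-01", "MKV", 2L),
    assembly_rows("unsupported", "2024-08-02", "MKV", 2L, support = FALSE)
  )
  sp <- time_split(recs)
  expect_identical(unique(sp$train$assembly_id), "tr")
  expect_identical(unique(sp$valid$assembly_id), "va")
  expect_identical(unique(sp$test$assembly_id), "te")
  # partitions are disjoint and cover all qualifying assemblies
  all_ids <- c(sp$train$assembly_id, sp$valid$assembly_id,
               sp$test$assembly_id)
  expect_false(any(duplicated(unique(all_ids))))
  expect_setequal(unique(all_ids), c("tr", "va", "te"))
  expect_error(time_split(recs, "2024-01-01", "2023-01-01"), "precede")
  bad <- recs; bad$date <- "not-a-date"
  expect_error(time_split(bad), "unparseable")
})

test_that("optimal mapping is globally optimal, not greedy", {
  # unique optimum on the diagonal
  m1 <- optimal_chain_mapping(rbind(c(0.9, 0.1), c(0.1, 0.9)))
  expect_identical(m1$assignment, c(1L, 2L))
  expect_equal(m1$total, 1.8)
  # greedy would take 0.95 first and be stuck with 0.1
  m2 <- optimal_chain_mapping(rbind(c(0.9, 0.95), c(0.9, 0.1)))
  expect_identical(m2$assignment, c(2L, 1L))
  expect_equal(m2$total, 0.95 + 0.9)
  m3 <- optimal_chain_mapping(matrix(0.7, 1, 1))
  expect_identical(m3$assignment, 1L)
  # fewer reference chains than test chains leaves a chain unmapped
  m4 <- optimal_chain_mapping(rbind(c(0.9), c(0.8)))
  expect_equal(sum(is.na(m4$assignment)), 1L)
})

test_that("assignment matches brute-force enumeration up to 5x5", {
  set.seed(71)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  for (n in 2:5) {
    for (r in 1:10) {
      M <- matrix(runif(n * n), n)
      best <- max(vapply(perms(seq_len(n)), function(p) {
        sum(M[cbind(seq_len(n), p)])
      }, numeric(1)))
      got <- optimal_chain_mapping(M)$total
      expect_equal(got, best, tolerance = 1e-12)
    }
  }
})

test_that("redundancy filter uses strict identity threshold per chain", {
  idf <- function(a, b) {
    key <- paste(a, b)
    c("t1 r1" = 0.9, "t2 r2" = 0.85,
      "u1 r1" = 0.9, "u2 r2" = 0.5,
      "v1 r1" = 0.8, "v2 r2" = 0.8)[key]
  }
  test_seqs <- list(c("t1", "t2"), c("u1", "u2"), c("v1", "v2"))
  ref_seqs <- list(c("r1", "r2"))
  ident <- function(a, b) {
    v <- idf(a, b)
    if (is.na(v)) 0 else unname(v)
  }
  kept <- redundancy_filter(test_seqs, ref_seqs, ident)
  expect_identical(kept, c(FALSE, TRUE, TRUE))
  # exactly 0.81 everywhere is removable, 0.8 is retained
  hi <- function(a, b) 0.81
  lo <- function(a, b) 0.8
  expect_false(redundancy_filter(list(c("x", "y")), ref_seqs, hi))
  expect_true(redundancy_filter(list(c("x", "y")), ref_seqs, lo))
  # a reference with fewer chains cannot cover a larger test complex
  expect_true(redundancy_filter(list(c("x", "y")), list("r1"), hi))
})

test_that("adding reference complexes only shrinks the retained set", {
  set.seed(72)
  mkid <- function() paste(sample(letters, 6, TRUE), collapse = "")
  test_seqs <- replicate(6, replicate(2, mkid()), simplify = FALSE)
  refs <- replicate(4, replicate(2, mkid()), simplify = FALSE)
  ident <- function(a, b) {
    set.seed(sum(utf8ToInt(paste(a, b))) %% 100000L)
    runif(1)
  }
  kept_small <- redundancy_filter(test_seqs, refs[1:2], ident)
  kept_big <- redundancy_filter(test_seqs, refs, ident)
  expect_true(all(kept_big <= kept_small))
})

test_that("size filters apply strict length bounds and copy cap", {
  seq_of <- function(n) paste(rep("M", n), collapse = "")
  recs <- rbind(
    # total 4073, max chain 499, copies 8: all bounds satisfied
    assembly_rows("ok", "2020-01-01", c(seq_of(499), seq_of(27)), c(8L, 3L)),
    # total 4491 >= 4200: removed even though chains and copies pass
    assembly_rows("total", "2020-01-01", c(seq_of(499), seq_of(499)),
                  c(8L, 1L)),
    # total exactly 4200 (strict bound): removed
    assembly_rows("boundary", "2020-01-01",
                  c(seq_of(499), seq_of(499), seq_of(208)), c(4L, 4L, 1L)),
    # max chain 500: removed
    assembly_rows("chain", "2020-01-01", seq_of(500), 1L),
    # 9 copies: removed
    assembly_rows("copies", "2020-01-01", seq_of(10), 9L)
  )
  kept <- af3_subset_filter(recs)
  expect_identical(unique(kept$assembly_id), "ok")
})
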