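test_that("negative sampling stays on transcripts with positives and caps at availability", {
  tx <- c(t1 = "UUUUU")
  pos <- tibble::tibble(transcript_id = "t1", position = 0L,
                        label = "positive", domain = "target")
  neg <- sample_negatives(tx, pos, ratio = 10, seed = 1)
  expect_equal(nrow(neg), 4)  # only 4 spare U
  expect_false(0L %in% neg$position)
  expect_true(all(neg$label == "negative"))
})

test_that("ratio mode approaches the requested pos:neg ratio on U-rich transcripts", {
  set.seed(3)
  tx <- stats::setNames(replicate(8, random_window(400)), paste0("tx", 1:8))
  pos <- dplyr::bind_rows(lapply(names(tx), function(id) {
    u <- which(strsplit(tx[[id]], "")[[1]] == "U") - 1L
    tibble::tibble(transcript_id = id, position = sample(u, 3),
                   label = "positive", domain = "target")
  }))
  neg <- sample_negatives(tx, pos, ratio = 10, seed = 9)
  expect_equal(nrow(neg), 10 * nrow(pos))  # ~100 U per transcript: no caps
  # all negatives are genuine undetected U on the same transcripts
  for (i in seq_len(nrow(neg))) {
    base <- substr(tx[[neg$transcript_id[i]]], neg$position[i] + 1,
                   neg$position[i] + 1)
    expect_equal(base, "U")
  }
  expect_equal(nrow(dplyr::inner_join(neg, pos,
                                      by = c("transcript_id", "position"))), 0)
})

test_that("negative sampling is seed-deterministic and row-order independent", {
  set.seed(5)
  tx <- c(a = random_window(200), b = random_window(200))
  pos <- tibble::tibble(transcript_id = c("a", "b", "a"),
                        position = c(10L, 30L, 50L),
                        label = "positive", domain = "source")
  # force positions to U so they are valid
  for (i in seq_len(nrow(pos))) {
    substr(tx[pos$transcript_id[i]], pos$position[i] + 1,
           pos$position[i] + 1) <- "U"
  }
  n1 <- sample_negatives(tx, pos, ratio = 3, seed = 7)
  n2 <- sample_negatives(tx, pos[c(3, 1, 2), ], ratio = 3, seed = 7)
  n3 <- sample_negatives(tx, pos, ratio = 3, seed = 8)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
})

test_that("'all' mode returns every undetected uridine", {
  tx <- c(t = "UAUUGU")
  pos <- tibble::tibble(transcript_id = "t", position = 0L,
                        label = "positive", domain = "source")
  neg <- sample_negatives(tx, pos, seed = 1, mode = "all")
  expect_equal(sort(neg$position), c(2L, 3L, 5L))
})

test_that("cv plan enumerates groups^2 folds with disjoint, covering groups", {
  pos <- sprintf("p%02d", 1:25)
  neg <- sprintf("n%03d", 1:250)
  plan <- make_cv_plan(pos, neg, groups = 6, seed = 2)
  expect_equal(nrow(plan$folds), 36)

  sizes <- table(plan$assignment$group[plan$assignment$label == "positive"])
  expect_lte(diff(range(sizes)), 1)

  # each record appears in exactly `groups` test sets, never in both sides
  appearances <- stats::setNames(rep(0, 275), c(pos, neg))
  for (f in plan$folds$fold) {
    ids <- rnadsn:::cv_fold_ids(plan, f)
    expect_length(intersect(ids$test, ids$train), 0)
    expect_equal(sort(c(ids$test, ids$train)), sort(c(pos, neg)))
    appearances[ids$test] <- appearances[ids$test] + 1
  }
  expect_true(all(appearances == 6))

  small <- make_cv_plan(pos[1:4], neg[1:4], groups = 2, seed = 1)
  expect_equal(nrow(small$folds), 4)
})

test_that("cv plans serialise to JSON and back", {
  plan <- make_cv_plan(sprintf("p%d", 1:12), sprintf("n%d", 1:12),
                       groups = 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_cv_plan(plan, path)
  rt <- read_cv_plan(path)
  expect_equal(rt$folds, plan$folds)
  expect_equal(rt$assignment, plan$assignment)
})

test_that("upsampling keeps every original and balances duplicate counts", {
  recs <- tibble::tibble(id = letters[1:5])
  up <- upsample_to_match(recs, 50, seed = 3)
  expect_equal(nrow(up), 50)
  counts <- table(up$id)
  expect_equal(sort(names(counts)), letters[1:5])
  expect_lte(diff(range(counts)), 1)

  expect_identical(upsample_to_match(recs, 5, seed = 1), recs)
  expect_identical(upsample_to_match(1:7, 23, seed = 5),
                   upsample_to_match(1:7, 23, seed = 5))
  expect_error(upsample_to_match(integer(0), 10), "empty")
  expect_error(upsample_to_match(1:5, 3), ">= 5")
})

test_that("paired streams upsample the target, cover each source record once", {
  src_w <- replicate(100, random_window(9))
  tgt_w <- replicate(30, random_window(9))
  mk <- function(w, domain) {
    rnadsn:::new_domain_dataset(
      encode_windows_test(w), rep(0:1, length.out = length(w)), domain,
      tibble::tibble(id = paste0(domain, seq_along(w))))
  }
  encode_windows_test <- function(w) {
    arr <- array(0, dim = c(length(w), 9, 4))
    for (i in seq_along(w)) arr[i, , ] <- one_hot_encode(w[i])
    arr
  }
  src <- mk(src_w, "source"); tgt <- mk(tgt_w, "target")
  stream <- pair_domains(src, tgt, batch = 10, seed = 6)
  expect_length(stream$batches, 10)
  src_idx <- unlist(lapply(stream$batches, `[[`, "source_idx"))
  tgt_idx <- unlist(lapply(stream$batches, `[[`, "target_idx"))
  expect_equal(sort(src_idx), 1:100)       # one pass, each source once
  expect_length(tgt_idx, 100)              # target upsampled to |source|
  expect_true(all(1:30 %in% tgt_idx))      # every target record survives
  for (b in stream$batches) {
    expect_equal(length(b$source_idx), length(b$target_idx))
  }
  stream2 <- pair_domains(src, tgt, batch = 10, seed = 6)
  expect_identical(stream$batches, stream2$batches)
})
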