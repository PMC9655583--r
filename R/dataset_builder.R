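#' Assemble a single-domain dataset of encoded windows
#'
#' Bundles one-hot encoded windows, 0/1 labels and per-record provenance for
#' one domain (source = tRNA + other RNAs, target = mRNA). Records are sorted
#' canonically by `(transcript_id, position)` first, so every later seeded
#' draw is independent of file row order.
#'
#' @param sites Site tibble with `window` column (see [extract_windows()]),
#'   or with `transcript_id`/`position` plus `transcripts` to extract from.
#' @param domain `"source"` or `"target"`; defaults to the table's single
#'   `domain` value.
#' @param transcripts Optional named sequence vector when windows still need
#'   extracting.
#' @param flank Flank size used if extraction is needed.
#' @return A `domain_dataset`: list with `encoded` (`N x L x 4` array),
#'   `labels` (integer 0/1), `domain`, and `provenance` (tibble with `id`).
#' @export
build_domain_dataset <- function(sites, domain = NULL, transcripts = NULL,
                                 flank = 20) {
  if (!"window" %in% names(sites)) {
    if (is.null(transcripts)) abort("`sites` has no windows and no `transcripts` given")
    sites <- extract_windows(sites, transcripts, flank = flank)
  }
  domain <- domain %||% unique(sites$domain)
  if (length(domain) != 1 || !domain %in% c("source", "target")) {
    abort("a domain_dataset holds exactly one domain ('source' or 'target')")
  }
  ord <- order(sites$transcript_id, sites$position)
  sites <- sites[ord, , drop = FALSE]
  sites$id <- paste0(sites$transcript_id, ":", sites$position)
  new_domain_dataset(
    encoded = encode_windows(sites$window),
    labels = as.integer(sites$label == "positive"),
    domain = domain,
    provenance = as_tibble(sites)
  )
}

new_domain_dataset <- function(encoded, labels, domain, provenance) {
  stopifnot(dim(encoded)[1] == length(labels),
            nrow(provenance) == length(labels))
  structure(
    list(encoded = encoded, labels = as.integer(labels), domain = domain,
         provenance = as_tibble(provenance)),
    class = "domain_dataset"
  )
}

#' @export
print.domain_dataset <- function(x, ...) {
  cat(sprintf("<domain_dataset: %s> %d windows of %d nt (%d positive, %d negative)\n",
              x$domain, length(x$labels), dim(x$encoded)[2],
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

# Row-subset a domain_dataset by integer indices (repeats allowed).
dataset_subset <- function(data, idx) {
  new_domain_dataset(
    encoded = data$encoded[idx, , , drop = FALSE],
    labels = data$labels[idx],
    domain = data$domain,
    provenance = data$provenance[idx, , drop = FALSE]
  )
}

#' Sample negative (undetected uridine) sites per transcript
#'
#' Negatives are drawn from the same transcripts that carry detected sites:
#' every `U` position on such a transcript that is not itself a positive is a
#' candidate. In `"ratio"` mode each transcript contributes up to
#' `ratio * n_positives_on_transcript` negatives, sampled without
#' replacement (the mRNA convention, 1:10 by default); `"all"` mode returns
#' every undetected uridine (the tRNA convention, giving roughly 1:3).
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param positives Site tibble of positive records.
#' @param ratio Negatives per positive in `"ratio"` mode.
#' @param seed Integer seed; draws are reproducible given the seed because
#'   transcripts and positions are canonically sorted before sampling.
#' @param mode `"ratio"` or `"all"`.
#' @return Site tibble of negative records in the same domain.
#' @export
sample_negatives <- function(transcripts, positives, ratio = 10, seed = 1,
                             mode = c("ratio", "all")) {
  mode <- match.arg(mode)
  if (mode == "ratio") assert_scalar_int(ratio, "ratio", min = 1)
  domain <- unique(positives$domain)
  if (length(domain) != 1) abort("positives must come from one domain")
  tx_ids <- sort(unique(positives$transcript_id))
  with_seed(seed, {
    out <- purrr::map(tx_ids, function(id) {
      if (!id %in% names(transcripts)) {
        abort(sprintf("unknown transcript: %s", id))
      }
      seq <- transcripts[[id]]
      pos_here <- sort(positives$position[positives$transcript_id == id])
      u_pos <- which(strsplit(seq, "", fixed = TRUE)[[1]] == "U") - 1L
      candidates <- setdiff(u_pos, pos_here)
      if (length(candidates) == 0) {
        warn(sprintf("transcript %s has positives but no spare U; no negatives drawn", id))
        return(NULL)
      }
      n <- if (mode == "all") {
        length(candidates)
      } else {
        min(ratio * length(pos_here), length(candidates))
      }
      drawn <- sort(sample(candidates, n, replace = FALSE))
      tibble(transcript_id = id, position = as.integer(drawn),
             label = "negative", domain = domain)
    })
    dplyr::bind_rows(out)
  })
}

#' Build the 6 x 6 cross-validation plan
#'
#' Positives and negatives are independently split into `groups` near-equal
#' groups; every (positive group, negative group) pairing defines one fold's
#' test set, giving `groups^2` folds (36 for the default 6). Each record
#' therefore appears in exactly `groups` test sets of its label across the
#' plan, and never in both sides of one fold.
#'
#' @param pos_ids,neg_ids Character vectors of record ids.
#' @param groups Number of groups per label (default 6).
#' @param seed Integer seed for the shuffles.
#' @return A `cv_plan`: list with `folds` (tibble of `fold`, `pos_group`,
#'   `neg_group`), `assignment` (tibble of `id`, `label`, `group`), `groups`.
#' @export
make_cv_plan <- function(pos_ids, neg_ids, groups = 6, seed = 1) {
  assert_scalar_int(groups, "groups", min = 2)
  if (length(pos_ids) < groups || length(neg_ids) < groups) {
    abort(sprintf("need at least %d ids per label", groups))
  }
  if (anyDuplicated(pos_ids) || anyDuplicated(neg_ids) ||
      length(intersect(pos_ids, neg_ids)) > 0) {
    abort("record ids must be unique within and across labels")
  }
  assign_groups <- function(ids, off) {
    ids <- sort(ids)
    shuffled <- with_seed(derive_seed(seed, off), sample(ids))
    tibble(id = shuffled, group = rep_len(seq_len(groups), length(ids)))
  }
  pos <- assign_groups(pos_ids, 1L); pos$label <- "positive"
  neg <- assign_groups(neg_ids, 2L); neg$label <- "negative"
  grid <- expand.grid(neg_group = seq_len(groups), pos_group = seq_len(groups))
  folds <- tibble(fold = seq_len(nrow(grid)),
                  pos_group = grid$pos_group, neg_group = grid$neg_group)
  structure(list(folds = folds,
                 assignment = dplyr::bind_rows(pos, neg)[, c("id", "label", "group")],
                 groups = groups, seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %d x %d = %d folds over %d records\n",
              x$groups, x$groups, nrow(x$folds), nrow(x$assignment)))
  invisible(x)
}

# Test/train record ids for one fold of a cv_plan.
cv_fold_ids <- function(plan, fold) {
  f <- plan$folds[plan$folds$fold == fold, ]
  if (nrow(f) != 1) abort(sprintf("no fold %s in plan", fold))
  a <- plan$assignment
  test <- a$id[(a$label == "positive" & a$group == f$pos_group) |
               (a$label == "negative" & a$group == f$neg_group)]
  list(test = test, train = setdiff(a$id, test))
}

#' Serialise / restore a cross-validation plan
#'
#' Plans are written as a small JSON document (group assignment plus fold
#' pairings) so a run can be repeated exactly.
#'
#' @param plan A `cv_plan`.
#' @param path File path.
#' @return `write_cv_plan()` returns `path` invisibly; `read_cv_plan()` the plan.
#' @export
write_cv_plan <- function(plan, path) {
  jsonlite::write_json(
    list(groups = plan$groups, seed = plan$seed,
         folds = plan$folds, assignment = plan$assignment),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cv_plan
#' @export
read_cv_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(folds = as_tibble(x$folds),
                 assignment = as_tibble(x$assignment),
                 groups = x$groups, seed = x$seed),
            class = "cv_plan")
}

#' Upsample records to a target count
#'
#' Stratified replication with a random top-up: every original record is kept
#' `floor(target_count / n)` times, and the remainder is drawn without
#' replacement, so each original appears at least once and duplicate counts
#' differ by at most one. Used to balance positives against negatives within
#' a training group and to match the target domain's size to the source's.
#'
#' @param records A tibble (rows are records) or a vector.
#' @param target_count Desired output size (`>= nrow/length` of `records`).
#' @param seed Integer seed.
#' @return Records of the requested size, same type as the input.
#' @export
upsample_to_match <- function(records, target_count, seed = 1) {
  n <- if (is.data.frame(records)) nrow(records) else length(records)
  if (n == 0) abort("cannot upsample an empty set of records")
  assert_scalar_int(target_count, "target_count", min = n)
  idx <- upsample_indices(n, target_count, seed)
  if (is.data.frame(records)) records[idx, , drop = FALSE] else records[idx]
}

upsample_indices <- function(n, target_count, seed) {
  if (target_count == n) return(seq_len(n))
  reps <- target_count %/% n
  extra <- target_count - reps * n
  idx <- rep(seq_len(n), reps)
  if (extra > 0) {
    idx <- c(idx, with_seed(derive_seed(seed, 3L), sample(seq_len(n), extra)))
  }
  with_seed(derive_seed(seed, 4L), sample(idx))
}

#' Pair source and target domains into equal-size training batches
#'
#' The network consumes one source and one target sub-batch per step, so the
#' (smaller) target domain is first upsampled to the source's size, both are
#' shuffled under the seed, and parallel sub-batches are cut. One pass over
#' the stream touches every source record exactly once.
#'
#' @param source,target `domain_dataset` objects.
#' @param batch Sub-batch size per domain.
#' @param seed Integer seed.
#' @return A `paired_stream`: list of steps, each holding `source_idx` and
#'   `target_idx` into the respective datasets.
#' @export
pair_domains <- function(source, target, batch = 64, seed = 1) {
  assert_scalar_int(batch, "batch", min = 1)
  n_s <- length(source$labels)
  n_t <- length(target$labels)
  if (n_s == 0 || n_t == 0) abort("both domains must be non-empty")
  t_idx <- if (n_t >= n_s) {
    with_seed(derive_seed(seed, 5L), sample(seq_len(n_t), n_s))
  } else {
    upsample_indices(n_t, n_s, derive_seed(seed, 5L))
  }
  s_idx <- with_seed(derive_seed(seed, 6L), sample(seq_len(n_s)))
  starts <- seq(1L, n_s, by = batch)
  batches <- lapply(starts, function(a) {
    b <- min(a + batch - 1L, n_s)
    list(source_idx = s_idx[a:b], target_idx = t_idx[a:b])
  })
  structure(list(batches = batches, batch = batch, seed = seed),
            class = "paired_stream")
}

#' @export
print.paired_stream <- function(x, ...) {
  cat(sprintf("<paired_stream> %d paired batches of up to %d per domain\n",
              length(x$batches), x$batch))
  invisible(x)
}
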