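#' Read transcript sequences from a FASTA file
#'
#' Loads a FASTA file into a named character vector of RNA sequences.
#' Sequences are uppercased and DNA-alphabet `T` is normalised to `U`, since
#' public modification-site tables are typically distributed against DNA
#' references. Duplicate identifiers are an error: downstream negative
#' sampling draws undetected uridines "from the same transcript", which is
#' only well defined when identifiers are unique.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector over the alphabet `ACGUN` (other IUPAC
#'   codes are preserved as-is and rejected later, at encoding time).
#' @seealso [extract_windows()], [one_hot_encode()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) abort(sprintf("empty FASTA file: %s", path))
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(sprintf("malformed FASTA at line %d of %s: expected '>' header", first, path))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate transcript identifier(s) in %s: %s",
                  path, paste(unique(dup), collapse = ", ")))
  }
  seqs <- chartr("Tt", "Uu", toupper(as.character(set)))
  if (any(!nzchar(seqs))) {
    abort(sprintf("empty sequence for transcript(s): %s",
                  paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  stats::setNames(toupper(seqs), ids)
}

#' Write transcript sequences to a FASTA file
#'
#' @param transcripts Named character vector as returned by [read_fasta()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(transcripts, path) {
  set <- Biostrings::BStringSet(transcripts)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a modification-site table
#'
#' Site tables are tab-separated with a header and at least the columns
#' `transcript_id`, `position` (0-based offset of the candidate uridine on
#' the transcript), `label` (`positive`/`negative`, or `1`/`0`) and `domain`
#' (`source`/`target`). Any further columns (e.g. `cell_line`, `technique`)
#' are carried along as tags.
#'
#' @param path Path to a TSV site table.
#' @return A tibble with normalised `label` and `domain` columns.
#' @export
read_sites <- function(path) {
  sites <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("transcript_id", "position", "label", "domain")
  missing <- setdiff(needed, names(sites))
  if (length(missing) > 0) {
    abort(sprintf("site table %s lacks column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  sites$transcript_id <- as.character(sites$transcript_id)
  sites$position <- as.integer(sites$position)
  sites$label <- normalize_labels(sites$label)
  if (!all(sites$domain %in% c("source", "target"))) {
    abort("`domain` must be 'source' or 'target'")
  }
  as_tibble(sites)
}

#' Write a modification-site table
#'
#' @param sites Site tibble (see [read_sites()] for the dialect).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sites <- function(sites, path) {
  readr::write_tsv(sites, path, progress = FALSE)
  invisible(path)
}

#' Import sites from a BED6 file
#'
#' The `chrom` field is interpreted as a transcript identifier and `chromStart`
#' (0-based) as the site position; `name` is kept as a tag and strand/score
#' are ignored — site tables are transcript-relative, sense strand resolved
#' upstream.
#'
#' @param path Path to a BED file (>= 3 columns, no header).
#' @param label Label to assign all records (`"positive"` or `"negative"`).
#' @param domain Domain to assign all records (`"source"` or `"target"`).
#' @return A site tibble in the [read_sites()] dialect.
#' @export
read_bed_sites <- function(path, label = "positive", domain = "target") {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3) abort(sprintf("BED file %s has fewer than 3 columns", path))
  out <- tibble(
    transcript_id = as.character(bed[[1]]),
    position = as.integer(bed[[2]]),
    label = normalize_labels(rep(label, nrow(bed))),
    domain = domain
  )
  if (ncol(bed) >= 4) out$name <- as.character(bed[[4]])
  out
}

normalize_labels <- function(label) {
  lab <- as.character(label)
  lab[lab %in% c("1", "pos", "positive", "TRUE")] <- "positive"
  lab[lab %in% c("0", "neg", "negative", "FALSE")] <- "negative"
  if (!all(lab %in% c("positive", "negative"))) {
    abort("labels must be 'positive'/'negative' (or 1/0)")
  }
  lab
}

#' Extract a fixed-length window centred on one site
#'
#' Returns the `2 * flank + 1`-nt subsequence of the transcript centred on
#' `position`. Positions falling outside the transcript are filled with `N`
#' and counted in `n_padded`, so every window has the same length and the
#' centre base keeps its coordinate.
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param transcript_id Transcript identifier.
#' @param position 0-based offset of the centre base on the transcript.
#' @param flank Number of bases on each side of the centre (window length
#'   `2 * flank + 1`; the default 20 gives the 41-nt windows used throughout).
#' @param check_center If `"warn"` (default), a centre base that is not `U`
#'   (and not `N` padding) triggers a warning; `"ignore"` stays silent.
#' @return A list with `seq` (character window) and `n_padded` (integer).
#' @export
extract_window <- function(transcripts, transcript_id, position, flank = 20,
                           check_center = c("warn", "ignore")) {
  check_center <- match.arg(check_center)
  assert_scalar_int(flank, "flank", min = 1)
  if (!transcript_id %in% names(transcripts)) {
    abort(sprintf("unknown transcript: %s", transcript_id))
  }
  seq <- transcripts[[transcript_id]]
  len <- nchar(seq)
  if (position < 0 || position >= len) {
    abort(sprintf("site %s:%d out of bounds (transcript length %d)",
                  transcript_id, position, len))
  }
  lo <- position - flank   # 0-based inclusive
  hi <- position + flank
  pad_left <- max(0L, -lo)
  pad_right <- max(0L, hi - (len - 1L))
  core <- substr(seq, max(0L, lo) + 1L, min(len - 1L, hi) + 1L)
  window <- paste0(strrep("N", pad_left), core, strrep("N", pad_right))
  center <- substr(window, flank + 1L, flank + 1L)
  if (check_center == "warn" && !center %in% c("U", "N")) {
    warn(sprintf("centre base at %s:%d is '%s', not U", transcript_id, position, center))
  }
  list(seq = window, n_padded = pad_left + pad_right)
}

#' Extract windows for a table of sites
#'
#' Vectorised companion of [extract_window()]: appends `window` and
#' `n_padded` columns to a site tibble. Positive sites whose centre base is
#' not `U` produce one summary warning (`N` is tolerated for padded windows).
#'
#' @param sites Site tibble ([read_sites()] dialect).
#' @param transcripts Named character vector of transcript sequences.
#' @param flank Flank size; window length is `2 * flank + 1`.
#' @param strict Drop windows that needed `N`-padding instead of keeping them.
#' @return `sites` with `window` and `n_padded` columns.
#' @export
extract_windows <- function(sites, transcripts, flank = 20, strict = FALSE) {
  res <- purrr::map2(sites$transcript_id, sites$position, function(id, pos) {
    extract_window(transcripts, id, pos, flank, check_center = "ignore")
  })
  sites$window <- purrr::map_chr(res, "seq")
  sites$n_padded <- purrr::map_int(res, ~ as.integer(.x$n_padded))
  center <- substr(sites$window, flank + 1L, flank + 1L)
  bad <- sites$label == "positive" & !center %in% c("U", "N")
  if (any(bad)) {
    warn(sprintf("%d positive site(s) whose centre base is not U", sum(bad)))
  }
  if (strict) sites <- sites[sites$n_padded == 0L, , drop = FALSE]
  as_tibble(sites)
}

#' One-hot encode a sequence window
#'
#' Encodes over the fixed channel order (A, C, G, U): `A -> (1,0,0,0)`,
#' `C -> (0,1,0,0)`, `G -> (0,0,1,0)`, `U -> (0,0,0,1)`. `N` (padding or
#' ambiguity) encodes as the all-zero row, so padded positions carry no
#' signal.
#'
#' @param window Character string over `{A,C,G,U,N}` (T is accepted as U).
#' @return An `L x 4` 0/1 matrix with column names `A,C,G,U`.
#' @export
one_hot_encode <- function(window) {
  chars <- strsplit(chartr("T", "U", toupper(window)), "", fixed = TRUE)[[1]]
  idx <- match(chars, RNA_BASES)
  bad <- which(is.na(idx) & chars != "N")
  if (length(bad) > 0) {
    abort(sprintf("invalid character '%s' at offset %d (0-based)",
                  chars[bad[1]], bad[1] - 1L))
  }
  m <- matrix(0, nrow = length(chars), ncol = 4L,
              dimnames = list(NULL, RNA_BASES))
  keep <- !is.na(idx)
  m[cbind(which(keep), idx[keep])] <- 1
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' Inverse of [one_hot_encode()]: one-hot rows map back to their base and
#' all-zero rows to `N`.
#'
#' @param matrix `L x 4` matrix whose rows are one-hot or all zero.
#' @return Character string of length `L`.
#' @export
decode_one_hot <- function(matrix) {
  if (ncol(matrix) != 4) abort("expected an L x 4 matrix")
  sums <- rowSums(matrix)
  if (any(!matrix %in% c(0, 1)) || any(!sums %in% c(0, 1))) {
    abort("rows must be one-hot (single 1) or all zero")
  }
  out <- rep("N", nrow(matrix))
  hot <- sums == 1
  out[hot] <- RNA_BASES[max.col(matrix[hot, , drop = FALSE])]
  paste(out, collapse = "")
}

# Encode a character vector of equal-length windows as an N x L x 4 array.
encode_windows <- function(windows) {
  L <- unique(nchar(windows))
  if (length(L) != 1) abort("windows must share one length")
  n <- length(windows)
  arr <- array(0, dim = c(n, L, 4L))
  mats <- lapply(windows, one_hot_encode)
  for (i in seq_len(n)) arr[i, , ] <- mats[[i]]
  arr
}
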