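# Reading, validating, encoding and splitting labelled DNA sequence sets.
#
# A labelled sequence is a list(id, bases, label) of class "dna_sequence";
# bases are uppercase over {A,C,G,T,N} and label is 0 (false splice site) or
# 1 (true splice site).  The one-hot channel order is fixed as A,T,C,G.

BASE_ORDER <- c("A", "T", "C", "G")

#' Construct a labelled DNA sequence
#'
#' @param id Record identifier.
#' @param bases Character scalar over A,C,G,T,N (case-insensitive).
#' @param label 0 (false splice site) or 1 (true splice site).
#' @return A `dna_sequence` object: list(id, bases, label).
#' @export
#' @examples
#' dna_sequence("s1", "acgtn", 1)
dna_sequence <- function(id, bases, label) {
  if (!is.character(bases) || length(bases) != 1L || nchar(bases) == 0L)
    stop("bases must be a single non-empty string")
  bases <- toupper(bases)
  bad <- regexpr("[^ACGTN]", bases)
  if (bad > 0L)
    stop("invalid character '", substr(bases, bad, bad),
         "' at position ", bad, " in sequence '", id, "'")
  if (!label %in% c(0, 1))
    stop("label must be 0 or 1 (got '", label, "')")
  structure(list(id = as.character(id), bases = bases,
                 label = as.integer(label)),
            class = "dna_sequence")
}

#' @export
print.dna_sequence <- function(x, ...) {
  b <- if (nchar(x$bases) > 40L) paste0(substr(x$bases, 1L, 40L), "...") else x$bases
  cat(sprintf("<dna_sequence> %s  label=%d  length=%d\n  %s\n",
              x$id, x$label, nchar(x$bases), b))
  invisible(x)
}

#' Read labelled DNA sequences
#'
#' Reads a labelled sequence dataset from either a two-column TSV
#' (`sequence<TAB>label`, no header) or a FASTA file whose headers carry a
#' `label=<0|1>` token after the record id.  Sequences are uppercased and
#' validated against the A,C,G,T,N alphabet; a record with a missing or
#' invalid label, or an invalid character, raises an error naming the line
#' (and character position).
#'
#' @param path Input file.
#' @param format `"auto"` (detect: a leading `>` means FASTA, otherwise by
#'   file extension), `"fasta"`, or `"tsv"`.
#' @return List of [dna_sequence()] records in file order.
#' @export
read_labelled_sequences <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (format == "auto") {
    format <- if (length(lines) && startsWith(lines[[1L]], ">")) "fasta"
              else if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) "fasta"
              else "tsv"
  }
  if (format == "tsv") .read_tsv_records(lines, path) else .read_fasta_records(lines, path)
}

.read_tsv_records <- function(lines, path) {
  keep <- nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 2L)
      stop(path, " line ", i, ": expected 2 tab-separated columns, found ",
           length(fields))
    lab <- suppressWarnings(as.integer(fields[[2L]]))
    if (is.na(lab) || !lab %in% c(0L, 1L))
      stop(path, " line ", i, ": invalid label '", fields[[2L]], "'")
    j <- j + 1L
    out[[j]] <- tryCatch(
      dna_sequence(paste0("seq", j), fields[[1L]], lab),
      error = function(e) stop(path, " line ", i, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  out
}

.read_fasta_records <- function(lines, path) {
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0L) stop(path, ": no FASTA records found")
  out <- vector("list", length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    i <- hdr[[k]]
    header <- sub("^>", "", lines[[i]])
    toks <- strsplit(trimws(header), "\\s+")[[1L]]
    id <- toks[[1L]]
    labtok <- grep("^label=", toks, value = TRUE)
    if (length(labtok) != 1L)
      stop(path, " line ", i, ": header of '", id,
           "' must carry exactly one label=<0|1> token")
    lab <- suppressWarnings(as.integer(sub("^label=", "", labtok)))
    if (is.na(lab) || !lab %in% c(0L, 1L))
      stop(path, " line ", i, ": invalid label token '", labtok, "'")
    body <- lines[seq(i + 1L, bounds[[k + 1L]] - 1L)]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0L)
      stop(path, " line ", i, ": record '", id, "' has no sequence")
    out[[k]] <- tryCatch(
      dna_sequence(id, paste(body, collapse = ""), lab),
      error = function(e) stop(path, " line ", i, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  out
}

#' Write labelled DNA sequences
#'
#' Inverse of [read_labelled_sequences()]: emits either the two-column TSV
#' dialect or FASTA with `label=` header tokens (LF line endings).
#'
#' @param seqs List of [dna_sequence()] records.
#' @param path Output file.
#' @param format `"tsv"` or `"fasta"` (default from the file extension).
#' @export
write_labelled_sequences <- function(seqs, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(vapply(seqs, function(s) paste0(s$bases, "\t", s$label), ""),
               con, sep = "\n")
  } else {
    writeLines(unlist(lapply(seqs, function(s)
      c(sprintf(">%s label=%d", s$id, s$label), s$bases))), con, sep = "\n")
  }
  invisible(path)
}

#' One-hot encode a DNA sequence
#'
#' Maps a length-`n_d` sequence to an (`n_d` x 4) binary matrix with the
#' channel order A,T,C,G: A -> (1,0,0,0), T -> (0,1,0,0), C -> (0,0,1,0),
#' G -> (0,0,0,1).  The ambiguous base N encodes as an all-zero row, so the
#' sequence length is preserved and no spurious information is injected.
#'
#' @param seq A [dna_sequence()] or a plain character scalar (label then
#'   defaults to `NA`).
#' @return An `encoded_sequence`: the matrix with column names A,T,C,G and
#'   attributes `label` and `id`.
#' @export
#' @examples
#' encode_sequence("ACGTAC")
encode_sequence <- function(seq) {
  if (is.character(seq)) seq <- list(id = NA_character_, bases = toupper(seq),
                                     label = NA_integer_)
  if (nchar(seq$bases) == 0L) stop("cannot encode an empty sequence")
  chars <- strsplit(seq$bases, "", fixed = TRUE)[[1L]]
  idx <- match(chars, BASE_ORDER)           # NA for N
  if (any(is.na(idx) & chars != "N"))
    stop("invalid character in sequence at position ",
         which(is.na(idx) & chars != "N")[1L])
  n <- length(chars)
  m <- matrix(0L, nrow = n, ncol = 4L, dimnames = list(NULL, BASE_ORDER))
  hit <- !is.na(idx)
  m[cbind(which(hit), idx[hit])] <- 1L
  structure(m, label = seq$label, id = seq$id, class = "encoded_sequence")
}

#' Decode a one-hot matrix back to a DNA sequence
#'
#' Inverse of [encode_sequence()] on {A,C,G,T}; an all-zero row decodes to
#' N.  A row that is not one-hot (more than one nonzero entry, or an entry
#' other than 0/1) is an error.
#'
#' @param enc An `encoded_sequence` or plain (n x 4) matrix.
#' @return A [dna_sequence()] (label `NA` becomes 0 is not assumed; the
#'   stored label attribute is carried through when present).
#' @export
decode_encoding <- function(enc) {
  m <- unclass(enc)
  if (!is.matrix(m) || ncol(m) != 4L) stop("expected an (n x 4) matrix")
  if (any(!m %in% c(0, 1))) stop("matrix entries must be 0 or 1")
  rs <- rowSums(m)
  if (any(rs > 1))
    stop("row ", which(rs > 1)[1L], " is not one-hot (row sum > 1)")
  bases <- rep("N", nrow(m))
  hit <- rs == 1
  bases[hit] <- BASE_ORDER[max.col(m[hit, , drop = FALSE])]
  lab <- attr(enc, "label")
  id <- attr(enc, "id")
  structure(list(id = if (is.null(id)) NA_character_ else id,
                 bases = paste(bases, collapse = ""),
                 label = if (is.null(lab)) NA_integer_ else lab),
            class = "dna_sequence")
}

#' Encode a whole dataset
#'
#' @param seqs List of [dna_sequence()] records (all of one length).
#' @return List of `encoded_sequence` matrices.
#' @export
encode_dataset <- function(seqs) lapply(seqs, encode_sequence)

#' Assemble encoded sequences into a model input batch
#'
#' Stacks encoded (n_d x 4) matrices into the 4-d array consumed by the
#' network: dim `(n_d, 4, 1, batch)`, i.e. a single-channel 2-d image per
#' sequence (the channel axis is required by the 2-d convolutions).
#'
#' @param encs List of `encoded_sequence` matrices of equal length.
#' @return Numeric array with dim `(n_d, 4, 1, length(encs))` and an integer
#'   `labels` attribute.
#' @export
batch_tensor <- function(encs) {
  nd <- nrow(encs[[1L]])
  if (!all(vapply(encs, nrow, 0L) == nd))
    stop("all sequences in a batch must have equal length")
  x <- array(0, c(nd, 4L, 1L, length(encs)))
  for (i in seq_along(encs)) x[, , 1L, i] <- encs[[i]]
  labels <- vapply(encs, function(e) {
    l <- attr(e, "label")
    if (is.null(l)) NA_integer_ else as.integer(l)
  }, 0L)
  attr(x, "labels") <- labels
  x
}

#' Random train/validation/test split
#'
#' Randomly partitions a dataset into train, validation and test parts with
#' the given ratios (default 0.8/0.1/0.1).  The permutation is driven solely
#' by `seed` (the caller's RNG state is left untouched); counts are
#' `floor(r1*n)` train, `floor(r2*n)` validation, remainder test, so sizes
#' are reproducible.
#'
#' @param data List of records (typically encoded sequences).
#' @param ratios Length-3 numeric summing to 1 (tolerance 1e-9).
#' @param seed Integer seed.
#' @return A `split_dataset`: list(train, validation, test, ratios, seed,
#'   indices) where `indices` gives each part's positions in `data`.
#' @export
split_dataset <- function(data, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- length(data)
  if (n < 3L) stop("need at least 3 records to split")
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9)
    stop("ratios must be three numbers summing to 1")
  perm <- with_local_seed(seed, sample.int(n))
  n_tr <- floor(ratios[[1L]] * n)
  n_va <- floor(ratios[[2L]] * n)
  idx <- list(train = perm[seq_len(n_tr)],
              validation = perm[n_tr + seq_len(n_va)],
              test = perm[seq(n_tr + n_va + 1L, n)])
  structure(list(train = data[idx$train],
                 validation = data[idx$validation],
                 test = data[idx$test],
                 ratios = ratios, seed = as.integer(seed), indices = idx),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf("<split_dataset> train=%d validation=%d test=%d (seed %d)\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}
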