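# Synthetic planted-motif splice-site datasets.
#
# The generator emulates balanced fixed-window splice-site corpora: every
# true sequence carries the canonical dimer (GT donor / AG acceptor) at a
# fixed offset, optionally surrounded by consensus-distributed flanking
# positions; false sequences are background draws whose window at the site
# offset is guaranteed NOT to be the dimer, except for a `decoy_rate`
# fraction that carries the bare dimer (without consensus flanks) to make
# the task harder.

#' Positional motif model
#'
#' @param dimer Two-base string, e.g. `"GT"` (donor-like) or `"AG"`
#'   (acceptor-like).
#' @param site_offset 0-based position of the dimer start in true sequences.
#' @param consensus Optional position-specific probabilities for the flanks:
#'   a list with matrices `before` and/or `after` (columns A,T,C,G, rows
#'   summing to 1).  Rows of `before` cover the positions immediately
#'   upstream of the dimer in sequence order (last row adjacent to the
#'   dimer); rows of `after` cover positions immediately downstream.
#' @param background Length-4 nucleotide probability vector (order A,T,C,G)
#'   for non-motif positions.
#' @return A `motif_model` object.
#' @export
motif_model <- function(dimer = "GT", site_offset = 70L, consensus = NULL,
                        background = rep(0.25, 4)) {
  dimer <- toupper(dimer)
  if (nchar(dimer) != 2L || grepl("[^ACGT]", dimer))
    stop("dimer must be two bases over A,C,G,T")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9 ||
      any(background < 0))
    stop("background must be a length-4 probability vector")
  if (!is.null(consensus)) {
    for (side in names(consensus)) {
      m <- consensus[[side]]
      if (!is.matrix(m) || ncol(m) != 4L ||
          any(abs(rowSums(m) - 1) > 1e-9) || any(m < 0))
        stop("consensus$", side, " must be a (k x 4) stochastic matrix")
    }
  }
  if (site_offset < 0L) stop("site_offset must be >= 0")
  structure(list(dimer = dimer, site_offset = as.integer(site_offset),
                 consensus = consensus, background = as.numeric(background)),
            class = "motif_model")
}

#' Canonical donor / acceptor motif defaults
#'
#' Convenience constructors for realistic splice-site motifs.  The donor
#' model plants GT with flanking probabilities shaped like the canonical
#' exon|GT-intron consensus (MAG|GTRAGT); the acceptor model plants AG
#' preceded by a pyrimidine-rich tract and followed by a G-biased first
#' exonic base.  Columns are in channel order A,T,C,G.
#'
#' @param site_offset 0-based dimer start (default 70, centering the site
#'   in a 141-base window).
#' @return A [motif_model()].
#' @export
donor_motif <- function(site_offset = 70L) {
  before <- rbind(c(0.35, 0.10, 0.35, 0.20),   # -3: M (A/C)
                  c(0.60, 0.10, 0.15, 0.15),   # -2: A
                  c(0.10, 0.05, 0.05, 0.80))   # -1: G
  after <- rbind(c(0.60, 0.05, 0.05, 0.30),    # +3: R (A/G)
                 c(0.70, 0.10, 0.10, 0.10),    # +4: A
                 c(0.10, 0.05, 0.05, 0.80),    # +5: G
                 c(0.15, 0.55, 0.15, 0.15))    # +6: T
  colnames(before) <- colnames(after) <- BASE_ORDER
  motif_model("GT", site_offset,
              consensus = list(before = before, after = after))
}

#' @rdname donor_motif
#' @export
acceptor_motif <- function(site_offset = 70L) {
  pyr <- c(0.08, 0.42, 0.42, 0.08)             # pyrimidine-rich (C/T)
  before <- rbind(pyr, pyr, pyr, pyr,
                  c(0.05, 0.25, 0.65, 0.05))   # -1 of AG: C-biased
  after <- rbind(c(0.25, 0.15, 0.15, 0.45))    # +1: G-biased
  colnames(before) <- colnames(after) <- BASE_ORDER
  motif_model("AG", site_offset,
              consensus = list(before = before, after = after))
}

#' Synthetic dataset configuration
#'
#' @param n Total number of sequences (even; classes are balanced).
#' @param length Sequence length n_d (typical fixed-window lengths are 141
#'   and 602).
#' @param motif A [motif_model()].
#' @param decoy_rate Probability that a false sequence carries the bare
#'   dimer at the site offset (difficulty control; 0 = cleanly separable,
#'   1 = label independent of the site position).
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n, length = 141L, motif = donor_motif(),
                             decoy_rate = 0, seed = 1L) {
  if (n %% 2L != 0L) stop("n must be even (balanced classes)")
  if (decoy_rate < 0 || decoy_rate > 1) stop("decoy_rate must be in [0, 1]")
  if (motif$site_offset > length - 2L)
    stop("site_offset ", motif$site_offset,
         " leaves no room for the dimer in length ", length)
  nb <- if (is.null(motif$consensus$before)) 0L else nrow(motif$consensus$before)
  na <- if (is.null(motif$consensus$after)) 0L else nrow(motif$consensus$after)
  if (motif$site_offset < nb || motif$site_offset + 2L + na > length)
    stop("consensus flanks do not fit in the sequence window")
  structure(list(n = as.integer(n), length = as.integer(length),
                 motif = motif, decoy_rate = decoy_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a balanced planted-motif dataset
#'
#' Emits `n/2` true sequences (dimer at the site offset, flanks drawn from
#' the consensus where given, everything else from the background) and
#' `n/2` false sequences (background draws whose site-offset 2-mer is
#' resampled to differ from the dimer, except for a `decoy_rate` fraction
#' that carries the bare dimer).  Byte-identical for identical config and
#' seed; the caller's RNG state is untouched.
#'
#' @param config A [synthetic_config()].
#' @return List of [dna_sequence()] records (true records first).
#' @export
generate_splice_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  m <- config$motif
  n2 <- config$n %/% 2L
  len <- config$length
  d1 <- m$site_offset + 1L                     # 1-based dimer columns
  dimer <- strsplit(m$dimer, "")[[1L]]
  with_local_seed(config$seed, {
    draw <- function(nrow, prob) matrix(sample(BASE_ORDER, nrow * len,
                                               replace = TRUE, prob = prob),
                                        nrow = nrow)
    true_m <- draw(n2, m$background)
    true_m[, d1] <- dimer[1L]
    true_m[, d1 + 1L] <- dimer[2L]
    cs <- m$consensus
    if (!is.null(cs$before)) {
      nb <- nrow(cs$before)
      for (r in seq_len(nb))
        true_m[, d1 - nb + r - 1L] <-
          sample(BASE_ORDER, n2, replace = TRUE, prob = cs$before[r, ])
    }
    if (!is.null(cs$after)) {
      for (r in seq_len(nrow(cs$after)))
        true_m[, d1 + 1L + r] <-
          sample(BASE_ORDER, n2, replace = TRUE, prob = cs$after[r, ])
    }
    false_m <- draw(n2, m$background)
    is_decoy <- stats::rbinom(n2, 1L, config$decoy_rate) == 1L
    false_m[is_decoy, d1] <- dimer[1L]
    false_m[is_decoy, d1 + 1L] <- dimer[2L]
    # non-decoys must NOT carry the dimer at the site: resample the 2-mer
    # from the background conditioned on != dimer
    redo <- which(!is_decoy & false_m[, d1] == dimer[1L] &
                    false_m[, d1 + 1L] == dimer[2L])
    while (length(redo) > 0L) {
      false_m[redo, d1] <- sample(BASE_ORDER, length(redo), replace = TRUE,
                                  prob = m$background)
      false_m[redo, d1 + 1L] <- sample(BASE_ORDER, length(redo),
                                       replace = TRUE, prob = m$background)
      redo <- redo[false_m[redo, d1] == dimer[1L] &
                     false_m[redo, d1 + 1L] == dimer[2L]]
    }
    mk <- function(mat, label, prefix) lapply(seq_len(nrow(mat)), function(i)
      structure(list(id = sprintf("%s_%05d", prefix, i),
                     bases = paste(mat[i, ], collapse = ""),
                     label = label),
                class = "dna_sequence"))
    c(mk(true_m, 1L, "true"), mk(false_m, 0L, "false"))
  })
}
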