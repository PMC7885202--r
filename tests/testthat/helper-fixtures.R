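# Shared fixtures: everything is generated in code at test time.

# tiny labelled TSV / FASTA files
write_tiny_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(vapply(rows, function(r) paste(r, collapse = "\t"), ""), path)
  path
}

write_tiny_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(records), path)
  path
}

# a small clean planted-motif dataset, encoded and split
tiny_split <- function(n = 120, len = 24, seed = 7, split_seed = 11) {
  cfg <- synthetic_config(n, len, motif = donor_motif(len %/% 2L),
                          decoy_rate = 0, seed = seed)
  split_dataset(encode_dataset(generate_splice_dataset(cfg)),
                seed = split_seed)
}

# random feature map
rand_map <- function(h = 8, w = 4, c = 3, n = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(h * w * c * n), c(h, w, c, n))
}

# random (x, y) batch for a length-`len` input
rand_batch <- function(len, n, seed = 1) {
  set.seed(seed)
  list(x = array(stats::rnorm(len * 4 * n), c(len, 4, 1, n)),
       y = stats::rbinom(n, 1, 0.5))
}

# a legal random genotype over the full primitive set
rand_genotype <- function(seed = 1, nodes = 4) {
  set.seed(seed)
  ops <- setdiff(primitive_set(), "zero")
  part <- function() lapply(seq_len(nodes), function(i)
    lapply(sample(i + 1, 2, replace = FALSE) - 1, function(p)
      list(op = sample(ops, 1), pred = p)))
  cell_genotype(part(), part(), nodes = nodes)
}
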