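# Independent oracles and tiny fixture builders shared across tests.

tiny_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

mk_calls <- function(contig, position, strand, coverage = 30,
                     p_value = 1e-4, fraction = 0.8, mod_type = "m6A") {
  data.frame(contig_id = contig, position = as.integer(position),
             strand = strand, mod_type = mod_type,
             coverage = as.integer(coverage), p_value = p_value,
             fraction = fraction, stringsAsFactors = FALSE)
}

# Exhaustive O(n*m) pairing oracle: tests every (plus, minus) call pair
# against the symmetric-ApT definition, independently of the package's
# keyed matching.
brute_force_sites <- function(calls, genome) {
  chars <- lapply(as.character(genome), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
  base_of <- function(ct, p) {
    v <- chars[[ct]]
    if (p < 0 || p >= length(v)) "N" else v[p + 1]
  }
  # drop calls whose strand base is not an adenine
  ok <- vapply(seq_len(nrow(calls)), function(i) {
    b <- base_of(calls$contig_id[i], calls$position[i])
    (calls$strand[i] == "+" && b == "A") ||
      (calls$strand[i] == "-" && b == "T")
  }, logical(1))
  calls <- calls[ok, , drop = FALSE]
  plus <- calls[calls$strand == "+", , drop = FALSE]
  minus <- calls[calls$strand == "-", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(plus))) {
    for (j in seq_len(nrow(minus))) {
      if (plus$contig_id[i] == minus$contig_id[j] &&
          minus$position[j] == plus$position[i] + 1 &&
          base_of(plus$contig_id[i], plus$position[i]) == "A" &&
          base_of(plus$contig_id[i], plus$position[i] + 1) == "T") {
        w <- plus$coverage[i] + minus$coverage[j]
        rows[[length(rows) + 1]] <- data.frame(
          contig = plus$contig_id[i], apt_start = plus$position[i],
          ratio = (plus$coverage[i] * plus$fraction[i] +
                   minus$coverage[j] * minus$fraction[j]) / w,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(contig = character(), apt_start = integer(),
                      ratio = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$contig, out$apt_start), , drop = FALSE]
}

# O(n^2) Kendall tau-b by exhaustive pair enumeration with tie correction.
tau_b_brute <- function(x, y) {
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  num <- sum(as.numeric(dx[up]) * dy[up])
  n0 <- as.numeric(sum(up))
  n1 <- as.numeric(sum(dx[up] == 0))
  n2 <- as.numeric(sum(dy[up] == 0))
  num / sqrt((n0 - n1) * (n0 - n2))
}

# Random calls on a random genome: positions anywhere; strand follows the
# base where it is A/T and is random (often invalid) on C/G.
random_call_fixture <- function(genome_len = 10000, n_calls = 200,
                                contig = "c1") {
  seq <- paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
               collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(seq, contig))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(genome_len, n_calls) - 1L
  strand <- ifelse(chars[pos + 1] == "A", "+",
            ifelse(chars[pos + 1] == "T", "-",
                   sample(c("+", "-"), n_calls, replace = TRUE)))
  calls <- mk_calls(contig, pos, strand,
                    coverage = sample(25:60, n_calls, replace = TRUE),
                    fraction = round(stats::runif(n_calls), 3))
  list(genome = genome, calls = calls)
}
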