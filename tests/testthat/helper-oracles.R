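# Independent oracles used across the suite. These deliberately share no
# code with the implementation: the aligner oracle is a full (unbanded)
# dynamic program, and the footprint oracle enumerates candidate intervals
# instead of scanning runs.

# Minimum bisulfite-aware edit cost (match 0, mismatch 1, gap 1) between a
# reference and a clone, by full DP over the whole matrix.
oracle_edit_cost <- function(ref_seq, clone_seq) {
  r <- strsplit(ref_seq, "")[[1]]
  c <- strsplit(clone_seq, "")[[1]]
  n <- length(r); m <- length(c)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      hit <- c[j] == r[i] || (r[i] == "C" && c[j] == "T")
      D[i + 1, j + 1] <- min(D[i, j] + (if (hit) 0L else 1L),
                             D[i, j + 1] + 1L,
                             D[i + 1, j] + 1L)
    }
  }
  D[n + 1, m + 1]
}

# Cost realized by an align_clone() position map, for comparison with the
# oracle's minimum: non-bisulfite mismatches + unaligned positions on
# either sequence.
map_cost <- function(map, ref_seq, clone_seq) {
  r <- strsplit(ref_seq, "")[[1]]
  c <- strsplit(clone_seq, "")[[1]]
  aligned <- which(!is.na(map))
  obs <- c[map[aligned]]
  expd <- r[aligned]
  mm <- sum(obs != expd & !(expd == "C" & obs == "T"))
  gaps <- (length(r) - length(aligned)) + (length(c) - length(aligned))
  mm + gaps
}

# Brute-force nucleosome footprint oracle: enumerate every interval whose
# bounds are flanking accessible GpCs (or amplicon edges) and whose
# interior informative GpCs are all inaccessible (>= 1 of them), keep
# maximal ones, filter by length.
oracle_footprints <- function(pos, state, amplicon_length,
                              min_length = 150L) {
  informative <- state != "undetermined"
  if (!any(informative)) return(NULL)
  pos <- pos[informative]
  acc <- state[informative] == "methylated"
  bounds_left <- c(-1L, pos[acc])    # -1 encodes the left edge
  bounds_right <- c(pos[acc], amplicon_length)
  cands <- list()
  for (lb in bounds_left) {
    for (rb in bounds_right) {
      if (rb <= lb) next
      start <- if (lb < 0) 0L else lb + 1L
      end <- if (rb >= amplicon_length) amplicon_length else rb
      interior <- pos[pos > lb & pos < rb]
      if (!length(interior)) next
      if (any(acc[match(interior, pos)])) next
      cands[[length(cands) + 1L]] <- c(start, end)
    }
  }
  if (!length(cands)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  }
  cm <- do.call(rbind, cands)
  # maximality: drop intervals strictly contained in another candidate
  keep <- vapply(seq_len(nrow(cm)), function(i) {
    !any(cm[, 1] <= cm[i, 1] & cm[, 2] >= cm[i, 2] &
           (cm[, 1] < cm[i, 1] | cm[, 2] > cm[i, 2]))
  }, logical(1))
  cm <- unique(cm[keep, , drop = FALSE])
  cm <- cm[order(cm[, 1]), , drop = FALSE]
  out <- data.frame(start = cm[, 1], end = cm[, 2],
                    length = cm[, 2] - cm[, 1])
  out[out$length >= min_length, , drop = FALSE]
}

# Direct in-silico bisulfite conversion of one molecule in the error-free
# limit, written independently of apply_assays(): every C converts except
# methylated CpGs and accessible GpC/GCG cytosines.
oracle_perfect_clone <- function(ref, truth) {
  bases <- strsplit(ref$sequence, "")[[1]]
  keep <- integer(0)
  keep <- c(keep, ref$cpg_sites[truth$cpg_methylation == 1] + 1L)
  keep <- c(keep, ref$gpc_sites[truth$gpc_accessible == 1] + 1L)
  if (length(ref$ambiguous_sites)) {
    ivs <- truth$nucleosome_intervals
    amb_acc <- vapply(ref$ambiguous_sites, function(p) {
      !nrow(ivs) || !any(ivs[, 1] <= p & p < ivs[, 2])
    }, logical(1))
    keep <- c(keep, ref$ambiguous_sites[amb_acc] + 1L)
  }
  cpos <- which(bases == "C")
  conv <- setdiff(cpos, keep)
  bases[conv] <- "T"
  paste(bases, collapse = "")
}
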