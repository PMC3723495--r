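#' Align a bisulfite clone to the reference amplicon
#'
#' Clones from amplicon bisulfite sequencing almost always match the
#' reference end to end, so a narrow banded global alignment (edit costs:
#' match 0, mismatch 1, gap 1) allowing a few indels suffices; it reduces
#' to the end-to-end gapless map whenever that map is optimal, and still
#' recovers compensating indel pairs that leave the length unchanged. A
#' reference C read as T is bisulfite conversion, not a mismatch, and is
#' scored as a match. Mapping quality is judged on the fraction of
#' non-bisulfite (non C-to-T) mismatches among aligned reference
#' positions; clones above `max_mismatch_fraction` are rejected.
#'
#' @param clone clone sequence (character).
#' @param reference a [reference_amplicon()].
#' @param max_mismatch_fraction rejection threshold on the non-C/T
#'   mismatch fraction (default 0.10).
#' @param max_indels half-width of the alignment band beyond the length
#'   difference (default 2).
#' @return list with elements `ok` (logical), `map` (integer vector over
#'   reference positions, 1-based clone index or NA for deleted), `
#'   mismatch_fraction`, `n_mismatch`, and `reason` when rejected.
#' @export
align_clone <- function(clone, reference, max_mismatch_fraction = 0.10,
                        max_indels = 2L) {
  stopifnot(inherits(reference, "reference_amplicon"))
  ref <- strsplit(reference$sequence, "")[[1]]
  cl <- strsplit(toupper(clone), "")[[1]]
  n <- length(ref)
  m <- length(cl)
  if (abs(m - n) > 0.10 * n) {
    return(list(ok = FALSE, map = NULL, mismatch_fraction = NA_real_,
                n_mismatch = NA_integer_,
                reason = sprintf("clone length %d outside +/-10%% of reference %d",
                                 m, n)))
  }
  # The banded DP yields the end-to-end gapless map whenever it is optimal
  # (equal lengths, no indels), and still recovers compensating
  # insertion/deletion pairs that leave the length unchanged.
  map <- banded_global_map(ref, cl, band = abs(m - n) + max_indels)
  if (is.null(map)) {
    return(list(ok = FALSE, map = NULL, mismatch_fraction = NA_real_,
                n_mismatch = NA_integer_,
                reason = "no alignment within band"))
  }
  aligned <- which(!is.na(map))
  obs <- cl[map[aligned]]
  exp <- ref[aligned]
  mm <- obs != exp & !(exp == "C" & obs == "T")
  frac <- sum(mm) / n
  if (frac > max_mismatch_fraction) {
    return(list(ok = FALSE, map = NULL, mismatch_fraction = frac,
                n_mismatch = sum(mm),
                reason = sprintf("mismatch fraction %.3f exceeds %.3f",
                                 frac, max_mismatch_fraction)))
  }
  list(ok = TRUE, map = map, mismatch_fraction = frac,
       n_mismatch = sum(mm), reason = NULL)
}

# Banded global edit-distance alignment of clone (cl) to reference (ref),
# bisulfite-aware (ref C vs clone T is a match). Returns the reference ->
# clone position map from the traceback, or NULL if the band is exceeded.
banded_global_map <- function(ref, cl, band) {
  n <- length(ref)
  m <- length(cl)
  band <- max(band, abs(m - n))
  INF <- .Machine$integer.max %/% 4L
  # D[i+1, j+1] = cost aligning ref[1..i] with cl[1..j], |i - j| <= band
  D <- matrix(INF, n + 1L, m + 1L)
  D[1L, 1L] <- 0L
  for (j in seq_len(min(band, m))) D[1L, j + 1L] <- j
  for (i in seq_len(min(band, n))) D[i + 1L, 1L] <- i
  for (i in seq_len(n)) {
    jlo <- max(1L, i - band)
    jhi <- min(m, i + band)
    for (j in jlo:jhi) {
      match <- cl[j] == ref[i] || (ref[i] == "C" && cl[j] == "T")
      sub <- D[i, j] + (if (match) 0L else 1L)
      del <- D[i, j + 1L] + 1L      # ref base unaligned (deletion in clone)
      ins <- D[i + 1L, j] + 1L      # clone base unaligned (insertion)
      D[i + 1L, j + 1L] <- min(sub, del, ins)
    }
  }
  if (D[n + 1L, m + 1L] >= INF) return(NULL)
  map <- rep(NA_integer_, n)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    here <- D[i + 1L, j + 1L]
    if (i > 0L && j > 0L) {
      match <- cl[j] == ref[i] || (ref[i] == "C" && cl[j] == "T")
      if (here == D[i, j] + (if (match) 0L else 1L)) {
        map[i] <- j
        i <- i - 1L; j <- j - 1L
        next
      }
    }
    if (i > 0L && here == D[i, j + 1L] + 1L) {
      i <- i - 1L
      next
    }
    j <- j - 1L
  }
  map
}
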