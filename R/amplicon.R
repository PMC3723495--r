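#' Annotate cytosine contexts on an amplicon top strand
#'
#' Classifies every cytosine of the top (sense) strand into the four
#' contexts that matter for dual methylation/accessibility calling:
#' \describe{
#'   \item{cpg}{C followed by G and not preceded by G (HCG): reports
#'     endogenous CpG methylation.}
#'   \item{gpc}{C preceded by G and not followed by G (GCH): reports
#'     M.CviPI accessibility.}
#'   \item{gcg}{C both preceded and followed by G (GCG): ambiguous between
#'     the endogenous and the enzymatic mark, excluded from both analyses.}
#'   \item{control}{C adjacent to no G: should always read as converted, so
#'     these positions measure bisulfite conversion efficiency.}
#' }
#'
#' All coordinates are 0-based positions of the C on the top strand.
#'
#' @param sequence single character string of A/C/G/T.
#' @return data.frame with columns `pos` (0-based) and `context`.
#' @export
annotate_contexts <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stopf("sequence contains non-ACGT characters")
  }
  n <- length(bases)
  idx <- which(bases == "C")
  if (length(idx) == 0L) {
    return(data.frame(pos = integer(0), context = character(0),
                      stringsAsFactors = FALSE))
  }
  prev_g <- idx > 1L & bases[pmax(idx - 1L, 1L)] == "G"
  next_g <- idx < n & bases[pmin(idx + 1L, n)] == "G"
  context <- ifelse(prev_g & next_g, "gcg",
             ifelse(next_g, "cpg",
             ifelse(prev_g, "gpc", "control")))
  data.frame(pos = idx - 1L, context = context, stringsAsFactors = FALSE)
}

#' Construct a reference amplicon
#'
#' Builds the annotated reference object used throughout the package: the
#' unconverted top-strand sequence plus the coordinates of CpG, GpC,
#' ambiguous (GCG) and control cytosines, and the transcription start site.
#'
#' @param name amplicon name (used as the "chromosome" in BED output).
#' @param sequence top-strand DNA string.
#' @param tss_position 0-based TSS coordinate within the amplicon.
#' @return object of class `reference_amplicon`.
#' @export
reference_amplicon <- function(name, sequence, tss_position) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  tss_position <- as.integer(tss_position)
  if (tss_position < 0L || tss_position >= len) {
    stopf("tss_position %d outside amplicon [0, %d)", tss_position, len)
  }
  ctx <- annotate_contexts(sequence)
  ref <- structure(list(
    name = name,
    sequence = sequence,
    length = len,
    tss_position = tss_position,
    cpg_sites = ctx$pos[ctx$context == "cpg"],
    gpc_sites = ctx$pos[ctx$context == "gpc"],
    ambiguous_sites = ctx$pos[ctx$context == "gcg"],
    control_c_sites = ctx$pos[ctx$context == "control"]
  ), class = "reference_amplicon")
  validate_reference(ref)
  ref
}

validate_reference <- function(ref) {
  sites <- c(ref$cpg_sites, ref$gpc_sites, ref$ambiguous_sites,
             ref$control_c_sites)
  if (anyDuplicated(sites)) stopf("site lists are not disjoint")
  if (length(sites) && (min(sites) < 0L || max(sites) >= ref$length)) {
    stopf("site coordinate outside [0, %d)", ref$length)
  }
  for (f in c("cpg_sites", "gpc_sites", "ambiguous_sites", "control_c_sites")) {
    if (is.unsorted(ref[[f]], strictly = TRUE)) {
      stopf("%s not strictly increasing", f)
    }
  }
  invisible(ref)
}

#' @export
print.reference_amplicon <- function(x, ...) {
  cat(sprintf(
    "<reference_amplicon> %s: %d bp, TSS @ %d\n  %d CpG, %d GpC, %d GCG (ambiguous), %d control C\n",
    x$name, x$length, x$tss_position, length(x$cpg_sites),
    length(x$gpc_sites), length(x$ambiguous_sites),
    length(x$control_c_sites)))
  invisible(x)
}

#' Generate a synthetic promoter amplicon
#'
#' Simulates a CpG-island-like promoter amplicon with CpG and GpC
#' dinucleotides planted at roughly the requested densities. Planting is
#' stratified (one motif per window of width 1/density) so that both site
#' types are spread along the whole amplicon rather than clumped; this
#' mirrors the dense, even GpC coverage a NOMe-seq amplicon needs to be
#' informative. A small number of GCG trinucleotides is planted so the
#' ambiguous-context path is exercised. The remaining background is drawn
#' from A/C/T, so every annotated site is either planted or arises from a
#' background C butting against a planted G.
#'
#' @param length amplicon length in bp (>= 300).
#' @param cpg_density target CpG sites per bp.
#' @param gpc_density target GpC sites per bp.
#' @param tss_offset 0-based TSS coordinate (default: midpoint).
#' @param seed integer seed; identical seeds give byte-identical amplicons.
#' @param name amplicon name.
#' @param n_gcg number of ambiguous GCG motifs to plant.
#' @return a [reference_amplicon()].
#' @export
generate_reference <- function(length, cpg_density, gpc_density,
                               tss_offset = NULL, seed = 1L,
                               name = "amplicon", n_gcg = 2L) {
  len <- as.integer(length)
  if (len < 300L) stopf("amplicon length must be >= 300 bp")
  n_cpg <- round(cpg_density * len)
  n_gpc <- round(gpc_density * len)
  if (n_cpg < 5L || n_gpc < 10L) {
    stopf("densities incompatible with length: need >= 5 CpG and >= 10 GpC, requested %d and %d",
          n_cpg, n_gpc)
  }
  if (3L * (n_cpg + n_gpc + n_gcg) > len) {
    stopf("densities incompatible with length: motifs will not fit")
  }
  tss_offset <- as.integer(tss_offset %||% (len %/% 2L))

  sequence <- with_seed(seed, {
    # C-rich background without G: all Gs come from planted motifs, so no
    # accidental GCG can form and planted site counts are stable.
    bases <- sample(c("A", "C", "T"), len, replace = TRUE,
                    prob = c(0.35, 0.30, 0.35))
    occupied <- logical(len)

    plant <- function(motif, n_target, bases, occupied) {
      w <- nchar(motif)
      motif_bases <- strsplit(motif, "")[[1]]
      bin <- len / n_target
      for (k in seq_len(n_target)) {
        lo <- as.integer(floor((k - 1) * bin)) + 1L
        hi <- min(as.integer(floor(k * bin)) - w, len - w + 1L)
        if (hi < lo) next
        cand <- lo:hi
        # keep 1 bp clearance so motifs cannot fuse into new contexts
        free <- vapply(cand, function(p) {
          span <- max(1L, p - 1L):min(len, p + w)
          !any(occupied[span])
        }, logical(1))
        cand <- cand[free]
        if (!length(cand)) next
        p <- if (length(cand) == 1L) cand else sample(cand, 1L)
        bases[p:(p + w - 1L)] <- motif_bases
        occupied[p:(p + w - 1L)] <- TRUE
      }
      list(bases = bases, occupied = occupied)
    }

    res <- plant("CG", n_cpg, bases, occupied)
    res <- plant("GC", n_gpc, res$bases, res$occupied)
    if (n_gcg > 0L) res <- plant("GCG", n_gcg, res$bases, res$occupied)
    paste(res$bases, collapse = "")
  })

  ref <- reference_amplicon(name, sequence, tss_offset)
  if (length(ref$cpg_sites) < 5L || length(ref$gpc_sites) < 10L) {
    stopf("densities incompatible with length: realized %d CpG / %d GpC sites",
          length(ref$cpg_sites), length(ref$gpc_sites))
  }
  ref
}

#' Write a reference amplicon as FASTA plus a BED site annotation
#'
#' @param ref a [reference_amplicon()].
#' @param fasta,bed output paths.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(ref, fasta, bed) {
  seqs <- Biostrings::DNAStringSet(ref$sequence)
  names(seqs) <- ref$name
  Biostrings::writeXStringSet(seqs, fasta)
  ctx <- data.frame(
    pos = c(ref$cpg_sites, ref$gpc_sites, ref$ambiguous_sites,
            ref$control_c_sites, ref$tss_position),
    name = c(rep("cpg", length(ref$cpg_sites)),
             rep("gpc", length(ref$gpc_sites)),
             rep("gcg", length(ref$ambiguous_sites)),
             rep("control", length(ref$control_c_sites)),
             "tss"),
    stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = ref$name,
    ranges = IRanges::IRanges(start = ctx$pos + 1L, width = 1L),
    name = ctx$name)
  rtracklayer::export(gr, bed, format = "BED")
  invisible(c(fasta = fasta, bed = bed))
}

#' Read a reference amplicon from FASTA (+ BED for the TSS)
#'
#' Site contexts are re-derived from the sequence (annotation is a pure
#' function of the top strand); the BED file is only needed to recover the
#' TSS coordinate, or `tss_position` can be given directly.
#'
#' @param fasta FASTA path with a single record.
#' @param bed optional BED path containing a record named `tss`.
#' @param tss_position optional 0-based TSS coordinate.
#' @return a [reference_amplicon()].
#' @export
read_reference <- function(fasta, bed = NULL, tss_position = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) stopf("reference FASTA must hold one record")
  if (is.null(tss_position)) {
    if (is.null(bed)) stopf("either bed or tss_position is required")
    gr <- rtracklayer::import(bed, format = "BED")
    tss <- gr[gr$name == "tss"]
    if (length(tss) != 1L) stopf("BED must contain exactly one 'tss' record")
    tss_position <- GenomicRanges::start(tss) - 1L
  }
  reference_amplicon(names(seqs)[1], as.character(seqs[[1]]), tss_position)
}
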