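#' Classify a molecule by its CpG methylation load
#'
#' Implements the single-molecule definitions used for time-course
#' populations: a molecule is `demethylated` (complete or near-complete
#' demethylation) when it carries at most `max_methylated` methylated CpG
#' dinucleotides; `hypermethylated` when at least `hyper_fraction` of its
#' assayed CpGs are methylated; otherwise `intermediate`. Undetermined
#' sites are excluded from both numerator and denominator. Molecules with
#' fewer than `min_assayed` determined CpGs are not classifiable and are
#' flagged `excluded`.
#'
#' @param profile a QC'd [call_sites()] profile.
#' @param max_methylated demethylated-class cutoff (default 2).
#' @param hyper_fraction hypermethylated-class cutoff (default 0.9).
#' @param min_assayed minimum determined CpG calls (default 5).
#' @return list with `methylation_class`, `mcpg_count`,
#'   `assayed_cpg_count`, `excluded`.
#' @export
classify_methylation <- function(profile, max_methylated = 2L,
                                 hyper_fraction = 0.9, min_assayed = 5L) {
  stopifnot(inherits(profile, "molecule_profile"))
  if (isFALSE(profile$qc_pass)) {
    stopf("clone '%s' failed conversion QC", profile$clone_id)
  }
  st <- profile$cpg_calls$state
  mcpg <- sum(st == "methylated")
  assayed <- sum(st != "undetermined")
  if (assayed < min_assayed) {
    message(sprintf("excluding clone '%s': only %d assayed CpGs",
                    profile$clone_id, assayed))
    return(list(methylation_class = NA_character_, mcpg_count = mcpg,
                assayed_cpg_count = assayed, excluded = TRUE))
  }
  cls <- if (mcpg <= max_methylated) "demethylated"
         else if (mcpg / assayed >= hyper_fraction) "hypermethylated"
         else "intermediate"
  list(methylation_class = cls, mcpg_count = mcpg,
       assayed_cpg_count = assayed, excluded = FALSE)
}

#' Call nucleosome footprints from single-molecule GpC accessibility
#'
#' A footprint is a maximal run of consecutive inaccessible GpC sites. Its
#' interval extends from just after the nearest flanking accessible GpC
#' (or from the amplicon start) to the nearest flanking accessible GpC on
#' the right (or the amplicon end): protection is claimed up to the
#' nearest evidence of accessibility. Undetermined GpCs are transparent —
#' they neither break nor bound a run (a missing observation is not
#' evidence of accessibility). Candidates shorter than `min_length` are
#' discarded.
#'
#' @param profile a [call_sites()] profile, or a data.frame with columns
#'   `pos` and `state` for the GpC track.
#' @param amplicon_length amplicon length in bp (runs may be bounded by
#'   the amplicon edges).
#' @param min_length minimum footprint length in bp (default 150).
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `length`, `left_bound`, `right_bound` (`"accessible_gpc"` or
#'   `"amplicon_edge"`); `NULL` if every GpC is undetermined (occupancy
#'   cannot be assessed).
#' @export
call_footprints <- function(profile, amplicon_length, min_length = 150L) {
  gpc <- if (inherits(profile, "molecule_profile")) profile$gpc_calls
         else profile
  informative <- gpc$state != "undetermined"
  if (!any(informative)) return(NULL)
  pos <- gpc$pos[informative]
  acc <- gpc$state[informative] == "methylated"  # enzyme-marked = accessible
  if (sum(informative) < 2L) {
    warnf("fewer than 2 informative GpC calls; footprints unreliable")
  }
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), left_bound = character(0),
                      right_bound = character(0), stringsAsFactors = FALSE)
  inacc_idx <- which(!acc)
  if (!length(inacc_idx)) return(empty)
  # maximal runs of consecutive inaccessible informative GpCs
  runs <- split(inacc_idx, cumsum(c(1L, diff(inacc_idx) != 1L)))
  rows <- lapply(runs, function(r) {
    first <- r[1]; last <- r[length(r)]
    if (first > 1L) {
      start <- pos[first - 1L] + 1L
      lb <- "accessible_gpc"
    } else {
      start <- 0L
      lb <- "amplicon_edge"
    }
    if (last < length(pos)) {
      end <- pos[last + 1L]
      rb <- "accessible_gpc"
    } else {
      end <- as.integer(amplicon_length)
      rb <- "amplicon_edge"
    }
    data.frame(start = start, end = end, length = end - start,
               left_bound = lb, right_bound = rb, stringsAsFactors = FALSE)
  })
  fp <- do.call(rbind, rows)
  rownames(fp) <- NULL
  fp[fp$length >= min_length, , drop = FALSE]
}

#' Classify TSS occupancy from called footprints
#'
#' @param footprints result of [call_footprints()]; `NULL` propagates an
#'   undetermined verdict.
#' @param tss 0-based TSS coordinate.
#' @return `"occupied"` if any retained footprint contains the TSS,
#'   `"depleted"` otherwise, `"undetermined"` if footprint calling was
#'   impossible.
#' @export
classify_tss_occupancy <- function(footprints, tss) {
  if (is.null(footprints)) return("undetermined")
  if (nrow(footprints) &&
      any(footprints$start <= tss & tss < footprints$end)) {
    "occupied"
  } else {
    "depleted"
  }
}

#' Summarize a clone population: methylation, occupancy and their joint
#'
#' Computes, over QC-passing classifiable molecules: per-CpG-site percent
#' methylation, the percent of demethylated molecules, the percent of
#' TSS-depleted molecules, and the 2x2 joint table of
#' demethylated-vs-not against TSS occupancy.
#'
#' @param profiles list of QC'd profiles (QC failures are skipped).
#' @param reference a [reference_amplicon()] (for TSS and length).
#' @param max_methylated,hyper_fraction,min_assayed see
#'   [classify_methylation()].
#' @param min_length see [call_footprints()].
#' @param digits decimals for reported percentages (default 1).
#' @return list of class `population_summary`: `n`, `per_site_pct`,
#'   `pct_demethylated`, `pct_tss_depleted`, `joint` (2x2 table),
#'   `molecules` (per-molecule data.frame).
#' @export
summarize_population <- function(profiles, reference, max_methylated = 2L,
                                 hyper_fraction = 0.9, min_assayed = 5L,
                                 min_length = 150L, digits = 1L) {
  stopifnot(inherits(reference, "reference_amplicon"))
  keep <- Filter(function(p) !isFALSE(p$qc_pass), profiles)
  if (!length(keep)) stopf("no QC-passing molecules to summarize")
  rows <- list()
  site_meth <- site_det <- setNames(numeric(length(reference$cpg_sites)),
                                    reference$cpg_sites)
  for (p in keep) {
    cls <- classify_methylation(p, max_methylated, hyper_fraction,
                                min_assayed)
    if (cls$excluded) next
    fp <- call_footprints(p, reference$length, min_length)
    occ <- classify_tss_occupancy(fp, reference$tss_position)
    st <- p$cpg_calls$state
    site_meth <- site_meth + (st == "methylated")
    site_det <- site_det + (st != "undetermined")
    rows[[p$clone_id]] <- data.frame(
      clone_id = p$clone_id,
      methylation_class = cls$methylation_class,
      mcpg_count = cls$mcpg_count,
      assayed_cpg_count = cls$assayed_cpg_count,
      tss_occupancy = occ, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stopf("no classifiable molecules to summarize")
  mol <- do.call(rbind, rows)
  rownames(mol) <- NULL
  n <- nrow(mol)
  demeth <- mol$methylation_class == "demethylated"
  depleted <- mol$tss_occupancy == "depleted"
  joint <- table(
    methylation = factor(ifelse(demeth, "demethylated", "not_demethylated"),
                         levels = c("demethylated", "not_demethylated")),
    occupancy = factor(mol$tss_occupancy,
                       levels = c("occupied", "depleted", "undetermined")))
  structure(list(
    n = n,
    per_site_pct = round_half_up(100 * site_meth / pmax(site_det, 1), digits),
    pct_demethylated = round_half_up(100 * sum(demeth) / n, digits),
    pct_tss_depleted = round_half_up(100 * sum(depleted) / n, digits),
    joint = joint,
    molecules = mol
  ), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf(
    "<population_summary> n = %d molecules\n  demethylated: %.1f%%  TSS-depleted: %.1f%%\n",
    x$n, x$pct_demethylated, x$pct_tss_depleted))
  print(x$joint)
  invisible(x)
}

#' Write called footprints for a clone set as BED
#'
#' One BED record per retained footprint; chrom is the amplicon name,
#' coordinates 0-based half-open, score the footprint length.
#'
#' @param profiles list of QC'd profiles.
#' @param reference a [reference_amplicon()].
#' @param path output BED path.
#' @param min_length see [call_footprints()].
#' @export
write_footprints_bed <- function(profiles, reference, path,
                                 min_length = 150L) {
  grl <- list()
  for (p in profiles) {
    fp <- call_footprints(p, reference$length, min_length)
    if (is.null(fp) || !nrow(fp)) next
    grl[[p$clone_id]] <- GenomicRanges::GRanges(
      seqnames = reference$name,
      ranges = IRanges::IRanges(start = fp$start + 1L, end = fp$end),
      name = p$clone_id, score = fp$length)
  }
  gr <- if (length(grl)) do.call(c, unname(grl))
        else GenomicRanges::GRanges()
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Render clone calls as a text lollipop matrix
#'
#' One row per clone; the CpG track uses M/U/N (methylated,
#' unmethylated, undetermined), the GpC track A/I/N (accessible,
#' inaccessible, undetermined). A header line marks the column nearest
#' the TSS with `*`.
#'
#' @param profiles list of profiles.
#' @param reference a [reference_amplicon()].
#' @param track `"cpg"` or `"gpc"`.
#' @return character vector of text lines (header + one per clone).
#' @export
render_lollipop <- function(profiles, reference, track = c("cpg", "gpc")) {
  track <- match.arg(track)
  field <- paste0(track, "_calls")
  code <- if (track == "cpg") {
    c(methylated = "M", unmethylated = "U", undetermined = "N")
  } else {
    c(methylated = "A", unmethylated = "I", undetermined = "N")
  }
  sites <- profiles[[1]][[field]]$pos
  tss_col <- which.min(abs(sites - reference$tss_position))
  header <- paste0(ifelse(seq_along(sites) == tss_col, "*", "-"),
                   collapse = "")
  ids <- vapply(profiles, `[[`, "", "clone_id")
  width <- max(nchar(ids))
  lines <- vapply(profiles, function(p) {
    paste0(formatC(p$clone_id, width = width, flag = "-"), " ",
           paste0(unname(code[p[[field]]$state]), collapse = ""))
  }, "")
  c(paste0(formatC("", width = width), " ", header), unname(lines))
}

#' Parse a rendered lollipop matrix back into call states
#'
#' Inverse of [render_lollipop()]: recovers the clone-by-site state
#' matrix from the text rendering.
#'
#' @param lines character vector from [render_lollipop()].
#' @param track `"cpg"` or `"gpc"`.
#' @return character matrix of states, rows named by clone id.
#' @export
parse_lollipop <- function(lines, track = c("cpg", "gpc")) {
  track <- match.arg(track)
  decode <- if (track == "cpg") {
    c(M = "methylated", U = "unmethylated", N = "undetermined")
  } else {
    c(A = "methylated", I = "unmethylated", N = "undetermined")
  }
  body <- lines[-1]
  ids <- sub("\\s.*", "", trimws(body))
  calls <- sub(".*\\s", "", trimws(body))
  mat <- t(vapply(strsplit(calls, ""),
                  function(ch) unname(decode[ch]),
                  character(nchar(calls[1]))))
  rownames(mat) <- ids
  mat
}
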