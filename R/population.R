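#' Describe one molecule class for population simulation
#'
#' A class couples a CpG methylation sampler with a nucleosome
#' configuration. The three canonical classes mirror what a reactivation
#' time course produces:
#' \itemize{
#'   \item `hypermethylated`: nearly every CpG methylated; the class
#'     definition (>= `hyper_fraction` of assayed CpGs) is enforced by
#'     construction so configured class counts are realized exactly.
#'   \item `demethylated`: at most `max_methylated` methylated CpGs per
#'     molecule (enforced by construction).
#'   \item `intermediate`: free binomial sampling at `meth_prob`, no
#'     enforcement.
#' }
#'
#' Nucleosome configuration (`tss_occupied_prob`): with this probability a
#' molecule carries a pair of abutting core particles spanning the TSS
#' (294 bp of protection, comfortably above the 150 bp footprint rule);
#' otherwise the region `tss +/- ndr_halfwidth` is kept nucleosome free.
#' In both cases flanks outside that central region are tiled with further
#' nucleosomes (`flank_occupied = TRUE`) or left open.
#'
#' @param name class label.
#' @param meth_prob per-CpG methylation probability.
#' @param enforce one of "none", "demethylated", "hypermethylated":
#'   whether sampled vectors are adjusted to guarantee class membership.
#' @param tss_occupied_prob probability the TSS is nucleosome covered.
#' @param flank_occupied tile nucleosomes over the flanks?
#' @param ndr_halfwidth half-width (bp) of the nucleosome-depleted region
#'   around the TSS for unoccupied molecules.
#' @param max_methylated,hyper_fraction class-definition thresholds used
#'   when `enforce` is not "none".
#' @return a `molecule_class_spec` list.
#' @export
molecule_class_spec <- function(name, meth_prob,
                                enforce = c("none", "demethylated",
                                            "hypermethylated"),
                                tss_occupied_prob = 1,
                                flank_occupied = TRUE,
                                ndr_halfwidth = 180L,
                                max_methylated = 2L,
                                hyper_fraction = 0.9) {
  enforce <- match.arg(enforce)
  stopifnot(meth_prob >= 0, meth_prob <= 1,
            tss_occupied_prob >= 0, tss_occupied_prob <= 1)
  structure(list(name = name, meth_prob = meth_prob, enforce = enforce,
                 tss_occupied_prob = tss_occupied_prob,
                 flank_occupied = flank_occupied,
                 ndr_halfwidth = as.integer(ndr_halfwidth),
                 max_methylated = as.integer(max_methylated),
                 hyper_fraction = hyper_fraction),
            class = "molecule_class_spec")
}

#' Default molecule classes (hypermethylated / demethylated / intermediate)
#'
#' Starting points for [population_spec()]; tweak fields (e.g.
#' `tss_occupied_prob`) per scenario.
#'
#' @return named list of [molecule_class_spec()] objects.
#' @export
default_classes <- function() {
  list(
    hypermethylated = molecule_class_spec(
      "hypermethylated", meth_prob = 0.98, enforce = "hypermethylated",
      tss_occupied_prob = 1),
    demethylated = molecule_class_spec(
      "demethylated", meth_prob = 0.03, enforce = "demethylated",
      tss_occupied_prob = 0),
    intermediate = molecule_class_spec(
      "intermediate", meth_prob = 0.5, enforce = "none",
      tss_occupied_prob = 0.5)
  )
}

#' Specify a simulated promoter molecule population
#'
#' @param n_molecules total molecule count (ignored when every class gives
#'   an exact `n`).
#' @param class_mix named numeric vector: either exact counts (integers
#'   summing to the population size) or fractions summing to 1. Names must
#'   match entries of `classes`.
#' @param classes named list of [molecule_class_spec()] objects; defaults
#'   cover hypermethylated / demethylated / intermediate.
#' @param nucleosome_width core-particle width in bp (default 147).
#' @param seed integer seed.
#' @return a `population_spec` list.
#' @export
population_spec <- function(n_molecules, class_mix,
                            classes = default_classes(),
                            nucleosome_width = 147L, seed = 1L) {
  if (is.null(names(class_mix)) || any(names(class_mix) == "")) {
    stopf("class_mix must be a named vector")
  }
  missing <- setdiff(names(class_mix), names(classes))
  if (length(missing)) stopf("unknown classes in class_mix: %s",
                             paste(missing, collapse = ", "))
  # integer vectors are exact counts, except a lone "1" which is read as
  # the trivial fraction vector
  counts_given <- all(class_mix == round(class_mix)) && sum(class_mix) != 1
  if (counts_given) {
    n_molecules <- as.integer(sum(class_mix))
    counts <- as.integer(class_mix)
  } else {
    if (abs(sum(class_mix) - 1) > 1e-8) {
      stopf("class_mix fractions must sum to 1")
    }
    counts <- floor(class_mix * n_molecules)
    # largest-remainder rounding
    rem <- class_mix * n_molecules - counts
    short <- n_molecules - sum(counts)
    if (short > 0) {
      add <- order(rem, decreasing = TRUE)[seq_len(short)]
      counts[add] <- counts[add] + 1L
    }
    counts <- as.integer(counts)
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 counts = setNames(counts, names(class_mix)),
                 classes = classes[names(class_mix)],
                 nucleosome_width = as.integer(nucleosome_width),
                 seed = as.integer(seed)),
            class = "population_spec")
}

# Sample the nucleosome intervals (0-based half-open, non-overlapping) for
# one molecule under a class spec.
sample_nucleosomes <- function(class_spec, ref, width) {
  tss <- ref$tss_position
  len <- ref$length
  ivs <- matrix(integer(0), ncol = 2)
  occupied <- runif(1) < class_spec$tss_occupied_prob
  if (occupied) {
    # two abutting core particles spanning the TSS: protection 2 * width
    a <- tss - width + sample(-60:60, 1)
    a <- max(0L, min(a, len - 2L * width))
    block <- c(a, a + 2L * width)
    ivs <- rbind(ivs, block)
    lo_edge <- block[1]
    hi_edge <- block[2]
  } else {
    lo_edge <- max(0L, tss - class_spec$ndr_halfwidth)
    hi_edge <- min(len, tss + class_spec$ndr_halfwidth)
  }
  if (class_spec$flank_occupied) {
    # tile leftwards then rightwards with 15-45 bp linkers
    pos <- lo_edge
    while (pos - width >= 0L) {
      gap <- sample(15:45, 1)
      s <- pos - gap - width
      if (s < 0L) break
      ivs <- rbind(ivs, c(s, s + width))
      pos <- s
    }
    pos <- hi_edge
    while (pos + width <= len) {
      gap <- sample(15:45, 1)
      s <- pos + gap
      if (s + width > len) break
      ivs <- rbind(ivs, c(s, s + width))
      pos <- s + width
    }
  }
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  storage.mode(ivs) <- "integer"
  dimnames(ivs) <- list(NULL, c("start", "end"))
  ivs
}

sample_methylation <- function(class_spec, n_cpg) {
  m <- rbinom(n_cpg, 1L, class_spec$meth_prob)
  if (class_spec$enforce == "demethylated") {
    excess <- sum(m) - class_spec$max_methylated
    if (excess > 0) {
      on <- which(m == 1L)
      off <- if (length(on) == 1L) on else sample(on, excess)
      m[off] <- 0L
    }
  } else if (class_spec$enforce == "hypermethylated") {
    need <- ceiling(class_spec$hyper_fraction * n_cpg) - sum(m)
    if (need > 0) {
      off <- which(m == 0L)
      on <- if (length(off) == 1L) off else sample(off, need)
      m[on] <- 1L
    }
  }
  m
}

#' Generate a ground-truthed population of promoter molecules
#'
#' Draws `spec$n_molecules` molecules. Each molecule carries a binary CpG
#' methylation vector over the reference CpG sites, a set of
#' non-overlapping nucleosome intervals, and the derived GpC accessibility
#' vector (a GpC is accessible iff it lies in no nucleosome interval).
#' Class counts given as exact counts are realized exactly.
#'
#' @param reference a [reference_amplicon()].
#' @param spec a [population_spec()].
#' @return list of `molecule_truth` objects (class label retained).
#' @export
generate_population <- function(reference, spec) {
  stopifnot(inherits(reference, "reference_amplicon"),
            inherits(spec, "population_spec"))
  if (spec$n_molecules == 0L) {
    warnf("n_molecules = 0: returning empty population")
    return(list())
  }
  n_cpg <- length(reference$cpg_sites)
  width <- spec$nucleosome_width
  with_seed(spec$seed, {
    out <- vector("list", spec$n_molecules)
    k <- 0L
    for (cls in names(spec$counts)) {
      cs <- spec$classes[[cls]]
      for (j in seq_len(spec$counts[[cls]])) {
        k <- k + 1L
        ivs <- sample_nucleosomes(cs, reference, width)
        acc <- gpc_accessibility(reference$gpc_sites, ivs)
        out[[k]] <- structure(list(
          molecule_id = sprintf("mol%d", k),
          class = cs$name,
          cpg_methylation = sample_methylation(cs, n_cpg),
          nucleosome_intervals = ivs,
          gpc_accessible = acc
        ), class = "molecule_truth")
      }
    }
    out
  })
}

# accessibility: 1 iff the GpC C coordinate falls inside no nucleosome
gpc_accessibility <- function(gpc_sites, intervals) {
  if (!length(gpc_sites)) return(integer(0))
  acc <- rep(1L, length(gpc_sites))
  if (nrow(intervals)) {
    for (r in seq_len(nrow(intervals))) {
      inside <- gpc_sites >= intervals[r, 1] & gpc_sites < intervals[r, 2]
      acc[inside] <- 0L
    }
  }
  acc
}

truth_tss_occupied <- function(truth, tss) {
  ivs <- truth$nucleosome_intervals
  nrow(ivs) > 0 && any(ivs[, 1] <= tss & tss < ivs[, 2])
}

#' Tabulate a simulated population's ground truth
#'
#' @param population list of molecule truths from [generate_population()].
#' @return data.frame with molecule_id, class, mcpg_count and nucleosome
#'   intervals encoded as `"start-end;start-end"`.
#' @export
truth_table <- function(population) {
  data.frame(
    molecule_id = vapply(population, `[[`, "", "molecule_id"),
    class = vapply(population, `[[`, "", "class"),
    mcpg_count = vapply(population, function(m) sum(m$cpg_methylation), 0L),
    nucleosome_intervals = vapply(population, function(m) {
      iv <- m$nucleosome_intervals
      if (!nrow(iv)) return("")
      paste(sprintf("%d-%d", iv[, 1], iv[, 2]), collapse = ";")
    }, ""),
    stringsAsFactors = FALSE)
}

#' Write a population truth table as TSV
#' @param population list of molecule truths.
#' @param path output TSV path.
#' @export
write_truth <- function(population, path) {
  write.table(truth_table(population), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
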