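#' Assay parameters for the in-silico NOMe-seq / bisulfite protocol
#'
#' @param gpc_methylase_efficiency probability an accessible GpC (or
#'   ambiguous GCG) cytosine is methylated by the GpC methyltransferase.
#' @param bisulfite_conversion_rate probability an unmethylated C reads T.
#' @param inappropriate_conversion_rate probability a methylated C reads T.
#' @param sequencing_error_rate per-base substitution probability, applied
#'   after conversion.
#' @param amplification_bias_weight multiplicative sampling weight per
#'   methylated CpG inside the primer footprints (see
#'   [amplify_with_bias()]).
#' @return an `assay_params` list.
#' @export
assay_params <- function(gpc_methylase_efficiency = 0.97,
                         bisulfite_conversion_rate = 0.995,
                         inappropriate_conversion_rate = 0.002,
                         sequencing_error_rate = 0.001,
                         amplification_bias_weight = 1.0) {
  p <- list(gpc_methylase_efficiency = gpc_methylase_efficiency,
            bisulfite_conversion_rate = bisulfite_conversion_rate,
            inappropriate_conversion_rate = inappropriate_conversion_rate,
            sequencing_error_rate = sequencing_error_rate,
            amplification_bias_weight = amplification_bias_weight)
  for (nm in names(p)) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stopf("%s must lie in [0, 1]", nm)
  }
  structure(p, class = "assay_params")
}

#' Error-free assay parameters (the perfect-chemistry limit)
#' @export
perfect_assay_params <- function() {
  assay_params(gpc_methylase_efficiency = 1,
               bisulfite_conversion_rate = 1,
               inappropriate_conversion_rate = 0,
               sequencing_error_rate = 0)
}

#' Push molecules through the simulated NOMe-seq / bisulfite protocol
#'
#' For each molecule: (1) GpC methyltransferase marks accessible GpC
#' cytosines with probability `gpc_methylase_efficiency` (nucleosome-covered
#' GpCs are never marked); (2) bisulfite converts every unmethylated C (any
#' context) to T with `bisulfite_conversion_rate`, while methylated Cs
#' (endogenous CpG or enzymatic GpC) stay C except for inappropriate
#' conversions; (3) per-base sequencing errors are applied last. Ambiguous
#' GCG cytosines are simulated as enzyme targets (accessible ones may be
#' marked) but carry no endogenous methylation; they are excluded from
#' calling anyway.
#'
#' @param molecules list of molecule truths from [generate_population()].
#' @param reference the [reference_amplicon()] the molecules were drawn on.
#' @param params an [assay_params()].
#' @param seed integer seed.
#' @param clones_per_molecule sequenced clones per molecule (default 1).
#' @return named character vector of clone sequences (bisulfite space),
#'   names `"mol<k>|clone<j>"`, with the truth table attached as
#'   `attr(, "truth")`.
#' @export
apply_assays <- function(molecules, reference, params = assay_params(),
                         seed = 1L, clones_per_molecule = 1L) {
  stopifnot(inherits(reference, "reference_amplicon"),
            inherits(params, "assay_params"))
  ref_bases <- strsplit(reference$sequence, "")[[1]]
  c_pos1 <- which(ref_bases == "C")            # 1-based C positions
  cpg1 <- reference$cpg_sites + 1L
  gpc1 <- reference$gpc_sites + 1L
  amb1 <- reference$ambiguous_sites + 1L
  alphabet <- c("A", "C", "G", "T")

  with_seed(seed, {
    out <- character(0)
    for (mol in molecules) {
      acc_amb <- if (length(amb1)) {
        gpc_accessibility(reference$ambiguous_sites, mol$nucleosome_intervals)
      } else integer(0)
      for (j in seq_len(clones_per_molecule)) {
        meth <- logical(length(ref_bases))
        meth[cpg1] <- mol$cpg_methylation == 1L
        # enzymatic marking of accessible GpC (and GCG) cytosines
        eff <- params$gpc_methylase_efficiency
        marked_gpc <- mol$gpc_accessible == 1L &
          rbinom(length(gpc1), 1L, eff) == 1L
        meth[gpc1[marked_gpc]] <- TRUE
        if (length(amb1)) {
          marked_amb <- acc_amb == 1L & rbinom(length(amb1), 1L, eff) == 1L
          meth[amb1[marked_amb]] <- TRUE
        }
        clone <- ref_bases
        unmeth_c <- c_pos1[!meth[c_pos1]]
        meth_c <- c_pos1[meth[c_pos1]]
        conv <- unmeth_c[rbinom(length(unmeth_c), 1L,
                                params$bisulfite_conversion_rate) == 1L]
        bad <- meth_c[rbinom(length(meth_c), 1L,
                             params$inappropriate_conversion_rate) == 1L]
        clone[c(conv, bad)] <- "T"
        if (params$sequencing_error_rate > 0) {
          hit <- which(rbinom(length(clone), 1L,
                              params$sequencing_error_rate) == 1L)
          for (p in hit) {
            clone[p] <- sample(setdiff(alphabet, clone[p]), 1L)
          }
        }
        out[[sprintf("%s|clone%d", mol$molecule_id, j)]] <-
          paste(clone, collapse = "")
      }
    }
    structure(out, truth = truth_table(molecules))
  })
}

#' Resample clones with methylation-dependent amplification bias
#'
#' Models a PCR assay designed to preferentially amplify unmethylated
#' templates: each clone is drawn with replacement with weight
#' `bias_weight ^ m`, where `m` is the number of retained (methylated) CpG
#' cytosines falling inside the primer footprints. `bias_weight = 1` is
#' unbiased; `bias_weight = 0` admits only clones with no methylated
#' primer CpG.
#'
#' @param clones named character vector of clone sequences, same length as
#'   the reference (as produced by [apply_assays()]).
#' @param reference the [reference_amplicon()].
#' @param primer_intervals 2-row matrix (start, end), 0-based half-open.
#' @param bias_weight weight in (0, 1]; 0 allowed as the hard-exclusion
#'   limit.
#' @param n_out number of clones to draw.
#' @param seed integer seed.
#' @return character vector of `n_out` sampled clones (names preserved).
#' @export
amplify_with_bias <- function(clones, reference, primer_intervals,
                              bias_weight, n_out, seed = 1L) {
  if (n_out <= 0) stopf("n_out must be positive")
  if (bias_weight < 0 || bias_weight > 1) stopf("bias_weight must be in [0, 1]")
  primer_intervals <- matrix(as.integer(primer_intervals), ncol = 2)
  if (any(primer_intervals < 0) ||
      any(primer_intervals > reference$length)) {
    stopf("primer intervals outside amplicon")
  }
  cpg0 <- reference$cpg_sites
  in_primer <- rep(FALSE, length(cpg0))
  for (r in seq_len(nrow(primer_intervals))) {
    in_primer <- in_primer |
      (cpg0 >= primer_intervals[r, 1] & cpg0 < primer_intervals[r, 2])
  }
  primer_cpg1 <- cpg0[in_primer] + 1L
  m <- vapply(clones, function(s) {
    sum(substring(s, primer_cpg1, primer_cpg1) == "C")
  }, 0L)
  w <- bias_weight ^ m
  w[m == 0L] <- 1   # 0^0 := 1 for the hard-exclusion limit
  if (all(w == 0)) stopf("all clones have zero amplification weight")
  with_seed(seed, {
    idx <- sample.int(length(clones), n_out, replace = TRUE, prob = w)
    clones[idx]
  })
}

#' Simulate a qPCR Ct table from true relative quantities
#'
#' Under 100% amplification efficiency a template at relative quantity `q`
#' crosses threshold `log2(q)` cycles earlier than a unit template:
#' `ct = base_ct - log2(q) + N(0, noise_sd)`, replicates independent.
#'
#' @param design data.frame with columns `assay`, `target`, `condition`,
#'   `day`, `true_quantity` (one row per measured well group).
#' @param base_ct Ct of a unit-quantity template.
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param n_replicates replicate wells per design row.
#' @param seed integer seed.
#' @return data.frame with columns assay, target, condition, day,
#'   replicate, ct.
#' @export
generate_ct_table <- function(design, base_ct = 25, noise_sd = 0.1,
                              n_replicates = 3L, seed = 1L) {
  stopifnot(is.data.frame(design),
            all(c("assay", "target", "condition", "day",
                  "true_quantity") %in% names(design)))
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (any(design$true_quantity <= 0)) stopf("true_quantity must be > 0")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(design)), function(i) {
      d <- design[i, ]
      data.frame(assay = d$assay, target = d$target,
                 condition = d$condition, day = d$day,
                 replicate = seq_len(n_replicates),
                 ct = base_ct - log2(d$true_quantity) +
                   rnorm(n_replicates, 0, noise_sd),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Write clone sequences as FASTA
#' @param clones named character vector of clone sequences.
#' @param path output FASTA path.
#' @export
write_clones <- function(clones, path) {
  seqs <- Biostrings::DNAStringSet(unname(unclass(clones)))
  names(seqs) <- names(clones)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read clone sequences from FASTA
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_clones <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}

#' Write / read the Ct table TSV dialect
#' @param ct data.frame as from [generate_ct_table()].
#' @param path TSV path.
#' @export
write_ct_table <- function(ct, path) {
  write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
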