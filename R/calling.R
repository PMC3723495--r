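#' Call per-site methylation and accessibility states for one clone
#'
#' At each CpG site the aligned clone base is read as: C = methylated,
#' T = unmethylated, anything else (including a site deleted in the
#' alignment) = undetermined. At each GpC site: C = the site was methylated
#' by the GpC methyltransferase, i.e. accessible; T = inaccessible; else
#' undetermined. Ambiguous GCG sites are skipped entirely. Control-context
#' cytosines are tallied into the observed bisulfite conversion rate.
#'
#' @param clone clone sequence.
#' @param alignment result of [align_clone()] (must have `ok = TRUE`).
#' @param reference a [reference_amplicon()].
#' @param clone_id identifier stored in the profile.
#' @return object of class `molecule_profile` with data.frames
#'   `cpg_calls` / `gpc_calls` (columns `pos`, `state`), the observed
#'   conversion rate, and control-cytosine counts.
#' @export
call_sites <- function(clone, alignment, reference, clone_id = "clone") {
  stopifnot(inherits(reference, "reference_amplicon"))
  if (!isTRUE(alignment$ok)) stopf("clone '%s' is not mapped", clone_id)
  cl <- strsplit(toupper(clone), "")[[1]]
  base_at <- function(pos0) {
    j <- alignment$map[pos0 + 1L]
    ifelse(is.na(j), NA_character_, cl[j])
  }
  state_of <- function(b) {
    ifelse(is.na(b), "undetermined",
    ifelse(b == "C", "methylated",
    ifelse(b == "T", "unmethylated", "undetermined")))
  }
  cpg_b <- vapply(reference$cpg_sites, base_at, "")
  gpc_b <- vapply(reference$gpc_sites, base_at, "")
  ctl_b <- vapply(reference$control_c_sites, base_at, "")
  n_conv <- sum(ctl_b == "T", na.rm = TRUE)
  n_unconv <- sum(ctl_b == "C", na.rm = TRUE)
  conv_rate <- if (n_conv + n_unconv > 0) n_conv / (n_conv + n_unconv)
               else NA_real_
  structure(list(
    clone_id = clone_id,
    cpg_calls = data.frame(pos = reference$cpg_sites,
                           state = state_of(cpg_b),
                           stringsAsFactors = FALSE),
    gpc_calls = data.frame(pos = reference$gpc_sites,
                           state = state_of(gpc_b),
                           stringsAsFactors = FALSE),
    conversion_rate_observed = conv_rate,
    n_control_informative = n_conv + n_unconv,
    qc_pass = NA
  ), class = "molecule_profile")
}

#' @export
print.molecule_profile <- function(x, ...) {
  cat(sprintf(
    "<molecule_profile> %s: %d/%d CpG methylated, %d/%d GpC accessible, conversion %.3f, qc %s\n",
    x$clone_id,
    sum(x$cpg_calls$state == "methylated"), nrow(x$cpg_calls),
    sum(x$gpc_calls$state == "methylated"), nrow(x$gpc_calls),
    x$conversion_rate_observed,
    ifelse(is.na(x$qc_pass), "untested", x$qc_pass)))
  invisible(x)
}

#' Bisulfite conversion quality control
#'
#' A clone passes QC when the observed conversion rate at control-context
#' cytosines (which carry no methylation and must read T) reaches
#' `min_conversion`. A clone with no informative control cytosines cannot
#' be judged; it is retained with `qc_pass = NA` and a warning.
#'
#' @param profile a [call_sites()] profile.
#' @param min_conversion threshold (default 0.95).
#' @return the profile with `qc_pass` filled in.
#' @export
conversion_qc <- function(profile, min_conversion = 0.95) {
  stopifnot(inherits(profile, "molecule_profile"))
  if (profile$n_control_informative == 0L ||
      is.na(profile$conversion_rate_observed)) {
    warnf("clone '%s': no informative control cytosines; QC undetermined",
          profile$clone_id)
    profile$qc_pass <- NA
  } else {
    profile$qc_pass <- profile$conversion_rate_observed >= min_conversion
  }
  profile
}

#' Align, call and QC a set of clones against a reference
#'
#' Convenience wrapper running [align_clone()], [call_sites()] and
#' [conversion_qc()] over a clone set. Unmappable clones are dropped with
#' a message; QC failures are retained but flagged.
#'
#' @param clones named character vector of clone sequences.
#' @param reference a [reference_amplicon()].
#' @param max_mismatch_fraction passed to [align_clone()].
#' @param min_conversion passed to [conversion_qc()].
#' @return list of `molecule_profile` objects.
#' @export
call_clones <- function(clones, reference, max_mismatch_fraction = 0.10,
                        min_conversion = 0.95) {
  ids <- names(clones) %||% sprintf("clone%d", seq_along(clones))
  out <- list()
  for (i in seq_along(clones)) {
    al <- align_clone(clones[[i]], reference, max_mismatch_fraction)
    if (!al$ok) {
      message(sprintf("dropping clone '%s': %s", ids[i], al$reason))
      next
    }
    prof <- call_sites(clones[[i]], al, reference, clone_id = ids[i])
    out[[ids[i]]] <- conversion_qc(prof, min_conversion)
  }
  out
}

#' Export per-clone calls as an M/U/N matrix TSV
#'
#' Rows are clones, columns are site coordinates; cells are M
#' (methylated / accessible), U (unmethylated / inaccessible) or N
#' (undetermined).
#'
#' @param profiles list of profiles from [call_clones()].
#' @param path output TSV path.
#' @param track `"cpg"` or `"gpc"`.
#' @return invisibly, the written character matrix.
#' @export
write_call_matrix <- function(profiles, path, track = c("cpg", "gpc")) {
  track <- match.arg(track)
  field <- paste0(track, "_calls")
  code <- c(methylated = "M", unmethylated = "U", undetermined = "N")
  mat <- t(vapply(profiles,
                  function(p) unname(code[p[[field]]$state]),
                  character(nrow(profiles[[1]][[field]]))))
  rownames(mat) <- vapply(profiles, `[[`, "", "clone_id")
  colnames(mat) <- profiles[[1]][[field]]$pos
  write.table(mat, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(mat)
}
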