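#' Rank GWAS-catalog associations and pick top loci
#'
#' Associations are deduplicated by variant id (keeping the smallest
#' discovery sample size) and ranked ascending by discovery sample size:
#' studies with smaller discovery populations are prioritized, giving
#' greater weight to variants with larger effects.  Ties break by
#' ascending p-value, then lexicographic vid, so the ranking is a total
#' order.  The top \code{top_k} associations are returned with ranks and
#' their locus windows.
#'
#' @param rows data.frame with columns \code{vid}, \code{trait},
#'   \code{discovery_n}, \code{p_value}, \code{ancestry}
#'   (semicolon-joined labels), optional \code{source}, \code{chrom},
#'   \code{pos}.  Rows should already be filtered to traits of interest.
#' @param top_k number of ranked associations to keep.
#' @param flank_bp locus flank used for the attached windows (needs
#'   \code{chrom} and \code{pos} columns; otherwise windows are omitted).
#' @return data.frame of ranked loci with a \code{rank} column (and
#'   \code{window_start}/\code{window_end}, 0-based half-open, when
#'   coordinates are available).  Empty input gives an empty result with
#'   a warning.
#' @export
rank_associations <- function(rows, top_k = 500L, flank_bp = 100000L) {
  if (nrow(rows) == 0) {
    warning("no associations supplied")
    return(cbind(rows, rank = integer(0)))
  }
  stopifnot(all(c("vid", "trait", "discovery_n", "p_value") %in% names(rows)),
            all(rows$discovery_n >= 1),
            all(rows$p_value > 0 & rows$p_value <= 1))
  ord <- order(rows$discovery_n, rows$p_value, rows$vid)
  rows <- rows[ord, , drop = FALSE]
  rows <- rows[!duplicated(rows$vid), , drop = FALSE]   # keeps smallest n
  rows <- head(rows, top_k)
  rows$rank <- seq_len(nrow(rows))
  if (all(c("chrom", "pos") %in% names(rows)) && nrow(rows) > 0) {
    rows$window_start <- pmax(0, rows$pos - 1 - flank_bp)
    rows$window_end <- rows$pos + flank_bp
  }
  rownames(rows) <- NULL
  rows
}

# recognized discovery-ancestry labels -> LD reference population
.ANCESTRY_MAP <- list(
  EUR = c("European", "European American", "Caucasian"),
  ASN = c("East Asian", "South Asian", "Asian"),
  AFR = c("African", "African American", "African-descent"),
  AMR = c("Hispanic", "Latino", "Hispanic/Latino", "Americas",
          "Native American"))

#' Choose the LD reference population for a discovery ancestry
#'
#' EUR is used whenever the index discovery sample included
#' European-descent populations; ASN for discovery populations of East or
#' South Asian descent only.  As a documented extension beyond those two
#' rules, purely African-descent ancestries map to AFR and
#' Hispanic/Latino ancestries to AMR; those results carry
#' \code{extension = TRUE} so users can override them.
#'
#' @param ancestry character vector of discovery ancestry labels
#'   (non-empty).
#' @return a population code (character) with attribute
#'   \code{extension} (\code{TRUE} when the mapping goes beyond the
#'   EUR/ASN rules).
#' @export
pick_ld_population <- function(ancestry) {
  if (length(ancestry) == 0) stop("ancestry must be non-empty")
  known <- unlist(.ANCESTRY_MAP, use.names = FALSE)
  bad <- setdiff(ancestry, known)
  if (length(bad))
    stop("unrecognized ancestry label(s): ", paste(bad, collapse = ", "),
         "; recognized: ", paste(known, collapse = ", "))
  grp <- vapply(ancestry, function(a) {
    names(.ANCESTRY_MAP)[vapply(.ANCESTRY_MAP, function(v) a %in% v,
                                logical(1))][1]
  }, character(1))
  if ("EUR" %in% grp)
    return(structure("EUR", extension = FALSE))
  if (all(grp == "ASN"))
    return(structure("ASN", extension = FALSE))
  if (all(grp == "AFR"))
    return(structure("AFR", extension = TRUE))
  if (all(grp == "AMR"))
    return(structure("AMR", extension = TRUE))
  # mixed non-European ancestries: fall back to the majority group,
  # flagged as an extension
  structure(names(which.max(table(grp))), extension = TRUE)
}
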