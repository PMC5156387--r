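#' Consequence severity table
#'
#' Ordered consequence vocabulary, most severe first, used to pick the
#' most likely deleterious annotation when several annotators disagree.
#' The default follows a Sequence-Ontology-style ordering; it is a
#' package choice (annotator consolidations differ) and fully
#' user-overridable — all behaviour re-derives from the table supplied.
#'
#' @param terms character vector of consequence terms, most severe
#'   first, no duplicates.
#' @return character vector of class \code{severity_table}.
#' @export
severity_table <- function(terms = c("stop_gained", "frameshift",
                                     "stop_lost", "splice_donor",
                                     "splice_acceptor", "inframe_indel",
                                     "missense", "splice_region",
                                     "utr5", "utr3", "synonymous",
                                     "intronic", "intergenic")) {
  if (anyDuplicated(terms)) stop("duplicate terms in severity table")
  structure(terms, class = "severity_table")
}

# consequence classes counted as exonic for the exome-enrichment rule
EXONIC_TERMS <- c("stop_gained", "frameshift", "stop_lost", "splice_donor",
                  "splice_acceptor", "inframe_indel", "missense",
                  "splice_region", "utr5", "utr3", "synonymous")

#' Consolidate multi-annotator consequence calls
#'
#' Per variant, the most likely deleterious annotation across sources is
#' assigned: the term with the smallest severity rank in \code{table}.
#' Deterministic, and invariant to call order and duplicated calls.
#'
#' @param calls data.frame with columns \code{vid}, \code{source},
#'   \code{term}.
#' @param table a \code{\link{severity_table}}.
#' @return named character vector, vid to consolidated term.
#' @export
consolidate_consequences <- function(calls, table = severity_table()) {
  stopifnot(all(c("vid", "term") %in% names(calls)))
  unknown <- setdiff(unique(calls$term), table)
  if (length(unknown))
    stop("consequence term(s) not in severity table: ",
         paste(unknown, collapse = ", "))
  rank <- match(calls$term, table)
  best <- tapply(rank, calls$vid, min)
  out <- setNames(unclass(table)[as.integer(best)], names(best))
  out[unique(calls$vid)]   # original first-appearance order
}

#' Exome-enrichment inclusion rule
#'
#' Inside priority gene regions the MAF floor is dropped entirely so
#' that singleton and doubleton observations are kept, and synonymous
#' (and UTR) variants are included alongside protein-changing ones.  The
#' rule returns \code{TRUE} for a variant inside \code{gene_regions}
#' whose consolidated term is exonic-class, \code{FALSE} for a variant
#' inside the regions with a non-exonic term, and \code{NA}
#' (not applicable — the filter abstains) outside the regions.
#'
#' @param chrom,pos variant coordinates (1-based position).
#' @param term consolidated consequence term.
#' @param gene_regions a \code{\link{region_set}} of priority genes.
#' @return logical (\code{TRUE}/\code{FALSE}/\code{NA}), vectorized.
#' @export
exome_inclusion_filter <- function(chrom, pos, term, gene_regions) {
  inside <- in_regions(gene_regions, chrom, pos)
  out <- rep(NA, length(pos))
  out[inside] <- term[inside] %in% EXONIC_TERMS
  out
}

#' Design-score filter
#'
#' Sites pass only with a design score strictly greater than
#' \code{min_score} (0.5 by default); sites with a missing score fail
#' unless \code{keep_unscored = TRUE}.
#'
#' @param sites data.frame with columns \code{vid} and
#'   \code{design_score}.
#' @param min_score strict lower bound.
#' @param keep_unscored whether missing scores pass.
#' @return list with data.frames \code{passing} and \code{failing}
#'   (a disjoint, exhaustive partition of the input rows).
#' @export
apply_design_filter <- function(sites, min_score = 0.5,
                                keep_unscored = FALSE) {
  sc <- sites$design_score
  pass <- !is.na(sc) & sc > min_score
  if (keep_unscored) pass <- pass | is.na(sc)
  list(passing = sites[pass, , drop = FALSE],
       failing = sites[!pass, , drop = FALSE])
}

#' Resolve category overlap into a design manifest
#'
#' A variant proposed under several content categories is assigned to
#' its highest-precedence category only, so that each variant is counted
#' once on the final array.  The manifest reports, per category, the
#' count before overlap removal (multi-membership) and after (unique
#' assignment).
#'
#' @param sites data.frame with columns \code{vid} and \code{categories}
#'   (comma-joined category tags, non-empty).
#' @param precedence character vector of categories, highest precedence
#'   first; must cover every category present.
#' @return object of class \code{design_manifest}: \code{counts}
#'   (category, n_before, n_after) and \code{assignment} (vid,
#'   category).
#' @export
dedup_categories <- function(sites, precedence) {
  stopifnot(all(c("vid", "categories") %in% names(sites)))
  cats <- strsplit(sites$categories, ",", fixed = TRUE)
  present <- unique(unlist(cats))
  missing <- setdiff(present, precedence)
  if (length(missing))
    stop("categories absent from precedence: ",
         paste(missing, collapse = ", "))
  if (any(lengths(cats) == 0))
    stop("every site needs at least one category")
  assigned <- vapply(cats, function(cc) precedence[min(match(cc, precedence))],
                     character(1))
  n_before <- vapply(precedence, function(cc)
    sum(vapply(cats, function(x) cc %in% x, logical(1))), integer(1))
  n_after <- vapply(precedence, function(cc) sum(assigned == cc), integer(1))
  counts <- data.frame(category = precedence,
                       n_before = unname(n_before),
                       n_after = unname(n_after),
                       stringsAsFactors = FALSE)
  structure(list(counts = counts,
                 assignment = data.frame(vid = sites$vid,
                                         category = assigned,
                                         stringsAsFactors = FALSE)),
            class = "design_manifest")
}

#' @export
print.design_manifest <- function(x, ...) {
  cat("design_manifest:", nrow(x$assignment), "variants,",
      sum(x$counts$n_after > 0), "categories in use\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}
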