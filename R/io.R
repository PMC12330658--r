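# Tab-separated readers/writers with schema validation, plus the per-gene
# count aggregation that feeds the Random Draw model.

VARIANT_REQUIRED <- c("gene_id", COVARIATE_NAMES)

#' Read a variant table
#'
#' Reads a tab-separated variant table (columns matched by name, not
#' position), validates the schema and value ranges, and applies the
#' ultra-rare filter: variants with allele frequency at or above `maf_bound`
#' (default 0.001, i.e. population frequency >= 0.1%) are excluded; the
#' excluded count is reported via a message and attached as attribute
#' `n_filtered`.
#'
#' @param path path to a TSV file with header `gene_id`, `AF`, `LOEUF`,
#'   `CCR`, `FDR_TADA_DD`, `obs_lof`, `exp_lof` and optional `label`,
#'   `score` columns.
#' @param maf_bound upper allele-frequency bound in (0, 0.5).
#' @return data.frame of validated variant records.
#' @export
read_variant_table <- function(path, maf_bound = 0.001) {
  stopifnot(maf_bound > 0, maf_bound < 0.5)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (nrow(tab) == 0L) stop("empty variant table: ", path)
  missing_cols <- setdiff(VARIANT_REQUIRED, names(tab))
  if (length(missing_cols))
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  keep <- c(VARIANT_REQUIRED, intersect(c("label", "score"), names(tab)))
  tab <- tab[, keep, drop = FALSE]
  for (nm in setdiff(keep, "gene_id"))
    if (!is.numeric(tab[[nm]]))
      stop("column ", nm, " must be numeric")
  if (any(tab$AF < 0)) stop("AF must be non-negative")
  if (any(tab$CCR < 0 | tab$CCR > 100)) stop("CCR must lie in [0, 100]")
  if (any(tab$FDR_TADA_DD < 0 | tab$FDR_TADA_DD > 1))
    stop("FDR_TADA_DD must lie in [0, 1]")
  if ("label" %in% keep && !all(tab$label %in% c(0, 1)))
    stop("label must be binary (1 = de novo, 0 = inherited)")
  rare <- tab$AF < maf_bound
  n_filtered <- sum(!rare)
  if (n_filtered > 0)
    message(n_filtered, " variant(s) removed by the AF < ", maf_bound,
            " ultra-rare filter")
  out <- tab[rare, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_filtered") <- n_filtered
  out
}

#' Write a variant table
#'
#' @param table data.frame of variant records.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate scored variants into per-gene classified counts
#'
#' For each gene, counts the likely-de-novo (`xd`: score strictly above the
#' threshold) and likely-inherited (`xh`: score at or below it) variants.
#' `xd + xh` equals the gene's variant count for any threshold.
#'
#' @param scored data.frame with `gene_id` and `score` columns.
#' @param threshold score threshold c.
#' @return data.frame with `gene_id`, `xd`, `xh`, one row per gene present
#'   in `scored`.
#' @examples
#' tab <- data.frame(gene_id = c("A", "A", "A"), score = c(0.8, 0.6, 0.1))
#' aggregate_counts(tab, 0.7)
#' @export
aggregate_counts <- function(scored, threshold) {
  stopifnot("gene_id" %in% names(scored))
  if (!"score" %in% names(scored) || anyNA(scored$score))
    stop("scored table must contain a complete 'score' column")
  if (nrow(scored) == 0L)
    return(data.frame(gene_id = character(0), xd = integer(0),
                      xh = integer(0), stringsAsFactors = FALSE))
  pred <- scored$score > threshold
  xd <- tapply(pred, scored$gene_id, sum)
  n <- tapply(pred, scored$gene_id, length)
  data.frame(gene_id = names(xd),
             xd = as.integer(xd),
             xh = as.integer(n - xd),
             stringsAsFactors = FALSE, row.names = NULL)
}
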