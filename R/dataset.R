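# Specimen tables: delimited-text I/O, the seven-category diet vocabulary,
# and species-mean aggregation (the unit on which the diet classifier runs).

.METRIC_COLUMNS <- c("rfi", "dne", "convexDNE", "ariaDNE", "ariaDNE_CV",
                     "opcr", "lnOA", "tritahi")

#' Load a specimen feature table from delimited text
#'
#' Reads a CSV/TSV of per-specimen records (taxon, clade, tooth locus, diet
#' label, metric values). Column names can be remapped via `column_map`
#' (names = canonical, values = names in the file). Diet labels must come
#' from the seven-category vocabulary; missing metric cells stay `NA` (absent
#' fields), never zeros.
#'
#' @param path file path.
#' @param sep field separator (default ",").
#' @param column_map optional named character vector remapping columns.
#' @param vocabulary admissible diet labels (default [dietVocabulary()]).
#' @return data frame of typed specimen records.
#' @export
loadSpecimenTable <- function(path, sep = ",", column_map = NULL,
                              vocabulary = dietVocabulary()) {
  if (!file.exists(path)) stop("table file does not exist: ", path)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) stop("mapped column '", src, "' not in file")
      names(df)[names(df) == src] <- canon
    }
  }
  required <- c("specimen_id", "species", "clade", "locus", "diet")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  badDiet <- which(!df$diet %in% vocabulary)
  if (length(badDiet))
    stop(sprintf("vocabulary error: row %d has unknown diet label '%s'",
                 badDiet[1], df$diet[badDiet[1]]))
  badLocus <- which(!df$locus %in% c("m2", "m3"))
  if (length(badLocus))
    stop(sprintf("row %d has locus '%s' (only m2/m3 are analysed)",
                 badLocus[1], df$locus[badLocus[1]]))
  dup <- duplicated(paste(df$specimen_id, df$locus))
  if (any(dup))
    stop(sprintf("duplication error: specimen '%s' locus '%s' appears twice",
                 df$specimen_id[which(dup)[1]], df$locus[which(dup)[1]]))
  for (m in intersect(.METRIC_COLUMNS, names(df)))
    df[[m]] <- as.numeric(df[[m]])
  df
}

#' Write a specimen table as delimited text
#'
#' @param table specimen data frame.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeSpecimenTable <- function(table, path, sep = ",") {
  write.table(table, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Aggregate specimen records into species means
#'
#' Per-species arithmetic means of each metric over the selected loci; m2 and
#' m3 of the same specimen count as separate observations when both loci are
#' selected (so two-tooth specimens are double-weighted, matching the pooled
#' m2+m3 treatment). Carried labels (clade, diet) must be consistent within
#' a species. Missing metric cells are dropped from that metric's mean.
#' The operation is idempotent: aggregating an already-aggregated table
#' returns it unchanged.
#'
#' @param records specimen data frame ([loadSpecimenTable()] shape).
#' @param loci subset of `c("m2", "m3")` to pool (default both).
#' @param metrics metric columns to average (default: those present).
#' @return data frame keyed by species with per-metric means, carried labels
#'   and a provenance count column `n_specimens`.
#' @export
speciesMeans <- function(records, loci = c("m2", "m3"),
                         metrics = intersect(.METRIC_COLUMNS, names(records))) {
  loci <- match.arg(loci, several.ok = TRUE)
  sel <- if ("locus" %in% names(records))
    records[records$locus %in% loci, , drop = FALSE] else records
  if (nrow(sel) == 0) stop("no records left after locus filter")
  split_ <- split(sel, sel$species)
  out <- lapply(split_, function(g) {
    for (lab in intersect(c("diet", "clade", "family"), names(g))) {
      u <- unique(g[[lab]])
      if (length(u) > 1)
        stop(sprintf("consistency error: species '%s' has conflicting %s labels (%s)",
                     g$species[1], lab, paste(u, collapse = ", ")))
    }
    means <- vapply(metrics, function(m) mean(g[[m]], na.rm = TRUE), numeric(1))
    means[is.nan(means)] <- NA_real_
    cbind(data.frame(species = g$species[1],
                     clade = if ("clade" %in% names(g)) g$clade[1] else NA,
                     diet = g$diet[1], n_specimens = nrow(g)),
          as.data.frame(as.list(means), check.names = FALSE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$species), , drop = FALSE]
}
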