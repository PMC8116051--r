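## Transcriptomic filtering: the dual-criteria preselection-DP signature,
## the curated ion-channel list filter, and heatmap-style scaling/clustering.

#' Criteria for the preselection-DP gene signature
#'
#' A gene belongs to the preselection-DP signature when the CD69- DP
#' population expresses it more than both its precursor (DN4) and its
#' immediate progeny (CD69+ DP) by more than `lfc_min` log2 fold change,
#' and it is either highly expressed (three-population combined expression
#' above `combined_expr_min` arbitrary units) or strongly induced (both
#' fold changes above `lfc_strong`). Recombination-machinery genes
#' (`Rag1`, `Rag2` by default) are excluded: their DP-restricted expression
#' reflects receptor rearrangement, not TCR tuning.
#'
#' @param lfc_min Minimum log2 fold change of DP69neg over each comparator
#'   (default 1).
#' @param combined_expr_min Combined expression threshold, a.u. (default
#'   2000). "Combined" is interpreted as the sum of the three population
#'   replicate-means; see `combined` for the alternatives.
#' @param lfc_strong Strong fold-change threshold (default 2); must exceed
#'   `lfc_min`.
#' @param exclude_genes Genes dropped regardless of criteria.
#' @param pseudocount Added to every population mean before fold changes
#'   (default 1 a.u.; inert for microarray intensities bounded away from
#'   zero, but guards synthetic zeros).
#' @param combined One of `"sum"` (default), `"dp69neg"`, `"max"`: how the
#'   combined-expression quantity is computed from the three population
#'   means.
#' @param log_scale If `TRUE`, input intensities are treated as already
#'   log2-scale: fold changes become differences of means and the combined
#'   expression is computed on the unlogged values.
#' @return An object of class `signature_criteria`.
#' @export
signature_criteria <- function(lfc_min = 1, combined_expr_min = 2000,
                               lfc_strong = 2,
                               exclude_genes = c("Rag1", "Rag2"),
                               pseudocount = 1,
                               combined = c("sum", "dp69neg", "max"),
                               log_scale = FALSE) {
  combined <- match.arg(combined)
  if (!is_number(lfc_min, 0) || !is_number(lfc_strong, 0) ||
      lfc_strong <= lfc_min)
    stop_fmt("invalid signature criteria: require lfc_strong > lfc_min > 0")
  if (!is_number(combined_expr_min, 0))
    stop_fmt("invalid signature criteria: combined_expr_min must be > 0")
  stopifnot(pseudocount >= 0)
  structure(list(lfc_min = lfc_min, combined_expr_min = combined_expr_min,
                 lfc_strong = lfc_strong, exclude_genes = exclude_genes,
                 pseudocount = pseudocount, combined = combined,
                 log_scale = log_scale),
            class = "signature_criteria")
}

population_means <- function(expr, samples, populations) {
  samples <- as.data.table(samples)
  missing <- setdiff(populations, unique(samples$population))
  if (length(missing))
    stop_fmt("precondition error: population(s) %s absent from sample annotation",
             paste(missing, collapse = ", "))
  vapply(populations, function(pp) {
    cols <- samples[population == pp, sample_id]
    rowMeans(expr[, cols, drop = FALSE])
  }, numeric(nrow(expr)))
}

#' Derive the preselection-DP gene signature
#'
#' Computes, per gene, the replicate-mean expression of the `DN4`,
#' `DP69neg`, and `DP69pos` populations, the two log2 fold changes
#' `L1 = log2((DP69neg + eps) / (DN4 + eps))` and
#' `L2 = log2((DP69neg + eps) / (DP69pos + eps))`, and applies the dual
#' criteria of [signature_criteria()]. Diagnostics record which branch
#' (high expression, strong fold change, or both) admitted each gene.
#'
#' @param expr Numeric matrix, genes x samples (nonnegative intensities).
#' @param samples data.frame with `sample_id` and `population` columns;
#'   populations `DN4`, `DP69neg`, `DP69pos` must each have >= 1 replicate.
#' @param criteria A [signature_criteria()] object.
#' @return A data.table of the admitted genes ordered by decreasing minimum
#'   fold change, with columns `gene`, `mean_DN4`, `mean_DP69neg`,
#'   `mean_DP69pos`, `lfc_vs_DN4`, `lfc_vs_DP69pos`, `combined_expr`,
#'   `branch` (`"expression"`, `"fold_change"`, or `"both"`).
#' @export
derive_preselection_signature <- function(expr, samples,
                                          criteria = signature_criteria()) {
  stopifnot(inherits(criteria, "signature_criteria"), is.matrix(expr))
  if (anyDuplicated(rownames(expr)))
    stop_fmt("validation error: duplicate gene ids")
  pops <- c("DN4", "DP69neg", "DP69pos")
  m <- population_means(expr, samples, pops)
  eps <- criteria$pseudocount
  if (criteria$log_scale) {
    l1 <- m[, "DP69neg"] - m[, "DN4"]
    l2 <- m[, "DP69neg"] - m[, "DP69pos"]
    lin <- 2^m
  } else {
    l1 <- log2((m[, "DP69neg"] + eps) / (m[, "DN4"] + eps))
    l2 <- log2((m[, "DP69neg"] + eps) / (m[, "DP69pos"] + eps))
    lin <- m
  }
  comb <- switch(criteria$combined,
                 sum = rowSums(lin),
                 dp69neg = lin[, "DP69neg"],
                 max = apply(lin, 1L, max))
  up <- l1 > criteria$lfc_min & l2 > criteria$lfc_min
  by_expr <- up & comb > criteria$combined_expr_min
  by_lfc <- l1 > criteria$lfc_strong & l2 > criteria$lfc_strong
  keep <- (by_expr | (up & by_lfc)) &
    !(rownames(expr) %in% criteria$exclude_genes)
  out <- data.table(gene = rownames(expr)[keep],
                    mean_DN4 = m[keep, "DN4"],
                    mean_DP69neg = m[keep, "DP69neg"],
                    mean_DP69pos = m[keep, "DP69pos"],
                    lfc_vs_DN4 = l1[keep],
                    lfc_vs_DP69pos = l2[keep],
                    combined_expr = comb[keep],
                    branch = fifelse(by_expr[keep] & by_lfc[keep], "both",
                                     fifelse(by_expr[keep], "expression",
                                             "fold_change")))
  out[order(-pmin(lfc_vs_DN4, lfc_vs_DP69pos))][]
}

#' Ion-channel filter parameters
#'
#' @param min_reads A candidate must exceed this read count in at least one
#'   RNA-seq sample (default 20).
#' @param padj_max BH-adjusted p-value cutoff; the candidate must be
#'   significant in at least one developmental stage (default 0.05).
#' @param always_include Genes kept regardless of the criteria (default
#'   `Tmie`).
#' @return An object of class `ion_filter_params`.
#' @export
ion_filter_params <- function(min_reads = 20, padj_max = 0.05,
                              always_include = "Tmie") {
  if (!is_number(min_reads, 0) || !is_number(padj_max, 0))
    stop_fmt("invalid ion filter params: thresholds must be > 0")
  structure(list(min_reads = min_reads, padj_max = padj_max,
                 always_include = always_include),
            class = "ion_filter_params")
}

#' Filter a curated ion-channel candidate list
#'
#' Keeps candidates that are well expressed (more than `min_reads` reads in
#' at least one sample) and differentially expressed between genotypes
#' (`padj < padj_max` in at least one developmental stage), plus the
#' `always_include` genes. Differential-expression results are consumed,
#' never computed: `de` is the output of an external DE tool.
#'
#' @param candidates Character vector of candidate gene names.
#' @param de data.frame with columns `gene`, `stage`, `padj`, and (unless
#'   `expr` is given) `max_reads`, the gene's maximum read count over
#'   samples.
#' @param params An [ion_filter_params()] object.
#' @param expr Optional genes x samples read-count matrix used for the
#'   expression criterion instead of `de$max_reads`.
#' @return Sorted character vector of retained genes. Candidates absent
#'   from `de` are retained only via `always_include`, with a warning.
#' @export
filter_ion_channels <- function(candidates, de,
                                params = ion_filter_params(), expr = NULL) {
  stopifnot(inherits(params, "ion_filter_params"))
  de <- as.data.table(de)
  need <- c("gene", "stage", "padj")
  missing_cols <- setdiff(need, names(de))
  if (length(missing_cols))
    stop_fmt("format error: de table missing column(s) %s",
             paste(missing_cols, collapse = ", "))
  if (nrow(de) && (any(de$padj < 0, na.rm = TRUE) ||
                   any(de$padj > 1, na.rm = TRUE)))
    stop_fmt("validation error: padj outside [0, 1]")
  absent <- setdiff(candidates, de$gene)
  if (length(absent))
    warn_fmt("%d candidate(s) absent from the DE table (kept only if always included): %s",
             length(absent), paste(head(absent, 5L), collapse = ", "))
  sig <- de[gene %in% candidates & !is.na(padj) & padj < params$padj_max,
            unique(gene)]
  expressed <- if (!is.null(expr)) {
    rn <- intersect(candidates, rownames(expr))
    rn[apply(expr[rn, , drop = FALSE], 1L, max) > params$min_reads]
  } else {
    if (!"max_reads" %in% names(de))
      stop_fmt("format error: de table needs a max_reads column when expr is not supplied")
    de[gene %in% candidates & max_reads > params$min_reads, unique(gene)]
  }
  sort(union(intersect(sig, expressed), params$always_include))
}

#' Replicate-average, row-scale, and cluster an expression submatrix
#'
#' Mirrors heatmap preprocessing: expression is averaged over biological
#' replicates within each (genotype, stage) sample group, each gene row is
#' z-scored (mean 0, SD 1; constant rows scale to zeros with a warning),
#' and rows are clustered by agglomerative hierarchical clustering on
#' Euclidean distance with complete linkage, cut into `k` groups. Cluster
#' labels are renumbered deterministically in the order of expression
#' during development: clusters whose scaled profile peaks in earlier
#' columns receive smaller labels (ties broken by the profile's weighted
#' center of mass, then by first gene name).
#'
#' @param expr Numeric matrix, genes x samples.
#' @param samples Optional data.frame with `sample_id` plus grouping
#'   columns (`genotype`, `stage`, or `population`); when supplied,
#'   replicate columns are averaged per group. Column order follows the
#'   order of first appearance in `samples`, so list samples in
#'   developmental order.
#' @param k Number of clusters (default 4); must not exceed the number of
#'   rows.
#' @return A list with `scaled` (row-z-scored, replicate-averaged matrix),
#'   `clusters` (named integer vector of labels, 1..k), and `tree` (the
#'   `hclust` object).
#' @export
scale_and_cluster <- function(expr, samples = NULL, k = 4L) {
  stopifnot(is.matrix(expr))
  if (!is_count(k, 1L)) stop_fmt("k must be a positive integer")
  if (nrow(expr) < k)
    stop_fmt("precondition error: need at least k = %d rows, have %d",
             k, nrow(expr))
  if (!is.null(samples)) {
    s <- as.data.table(samples)
    grp_cols <- intersect(c("genotype", "stage", "population"), names(s))
    if (!length(grp_cols))
      stop_fmt("format error: samples needs genotype/stage/population columns")
    s[, grp := do.call(paste, c(.SD, sep = ".")), .SDcols = grp_cols]
    groups <- unique(s$grp)
    expr <- vapply(groups, function(g) {
      cols <- s[grp == g, sample_id]
      rowMeans(expr[, cols, drop = FALSE])
    }, numeric(nrow(expr)))
  }
  mu <- rowMeans(expr)
  sdev <- apply(expr, 1L, sd)
  flat <- sdev == 0 | !is.finite(sdev)
  if (any(flat)) {
    warn_fmt("%d constant row(s) scaled to zeros", sum(flat))
    sdev[flat] <- 1
  }
  scaled <- (expr - mu) / sdev
  tree <- hclust(dist(scaled, method = "euclidean"), method = "complete")
  raw <- cutree(tree, k = k)
  ## renumber clusters by developmental order of their mean profile peak
  prof <- vapply(seq_len(k), function(g)
    colMeans(scaled[raw == g, , drop = FALSE]), numeric(ncol(scaled)))
  prof <- matrix(prof, ncol = k)
  peak <- apply(prof, 2L, which.max)
  com <- apply(prof, 2L, function(x) {
    w <- x - min(x)
    if (sum(w) == 0) return(mean(seq_along(x)))
    sum(w * seq_along(x)) / sum(w)
  })
  first_gene <- vapply(seq_len(k), function(g)
    sort(rownames(scaled)[raw == g])[1L], character(1L))
  ord <- order(peak, com, first_gene)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  clusters <- setNames(relabel[raw], rownames(scaled))
  list(scaled = scaled, clusters = clusters, tree = tree)
}

#' Read a GEO series-matrix file
#'
#' Minimal parser for the NCBI GEO "series matrix" text format: metadata
#' lines start with `!`, and the expression table sits between
#' `!series_matrix_table_begin` and `!series_matrix_table_end` with an
#' `ID_REF` key column and one column per sample accession. Sample titles
#' are taken from the `!Sample_title` line.
#'
#' @param path Path to an (uncompressed) series-matrix text file.
#' @param id_map Optional data.frame with columns `id` and `gene` mapping
#'   platform probe ids to gene symbols; probe rows mapping to the same
#'   gene are averaged. Without it, `ID_REF` values are used as row names
#'   unchanged.
#' @return A list with `expr` (matrix, rows = probes or genes, columns =
#'   sample accessions) and `samples` (data.table of `sample_id`, `title`).
#' @export
read_geo_series_matrix <- function(path, id_map = NULL) {
  lines <- readLines(path)
  unquote <- function(x) gsub('^"|"$', "", x)
  title_line <- grep("^!Sample_title\\b", lines, value = TRUE)
  acc_line <- grep("^!Sample_geo_accession\\b", lines, value = TRUE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (!length(beg) || !length(end) || end[1L] <= beg[1L] + 1L)
    stop_fmt("format error: no series matrix table in %s", path)
  tab <- fread(text = lines[(beg[1L] + 1L):(end[1L] - 1L)], sep = "\t")
  setnames(tab, unquote(names(tab)))
  ids <- unquote(as.character(tab[[1L]]))
  expr <- as.matrix(tab[, -1L])
  mode(expr) <- "numeric"
  rownames(expr) <- ids
  titles <- if (length(title_line))
    unquote(strsplit(title_line[1L], "\t")[[1L]][-1L]) else
      rep(NA_character_, ncol(expr))
  accs <- if (length(acc_line))
    unquote(strsplit(acc_line[1L], "\t")[[1L]][-1L]) else colnames(expr)
  samples <- data.table(sample_id = colnames(expr),
                        accession = accs[seq_len(ncol(expr))],
                        title = titles[seq_len(ncol(expr))])
  if (!is.null(id_map)) {
    id_map <- as.data.table(id_map)
    stopifnot(all(c("id", "gene") %in% names(id_map)))
    keep <- rownames(expr) %in% id_map$id
    g <- id_map[match(rownames(expr)[keep], id), gene]
    expr <- rowsum(expr[keep, , drop = FALSE], group = g) /
      as.vector(table(g)[sort(unique(g))])
  }
  list(expr = expr, samples = samples[])
}

#' Map ImmGen Phase-1 sample titles to population labels
#'
#' Recognizes the thymocyte populations `T.DN4.Th` (DN4), `T.DP.Th`
#' (preselection CD69- DP), and `T.DP69+.Th` (CD69+ DP) in ImmGen sample
#' titles such as `"T.DP69+.Th#2"`; other titles map to `NA`.
#'
#' @param titles Character vector of sample titles.
#' @return Character vector of `DN4` / `DP69neg` / `DP69pos` / `NA`.
#' @export
map_immgen_populations <- function(titles) {
  out <- rep(NA_character_, length(titles))
  out[grepl("^T\\.DN4\\.Th", titles)] <- "DN4"
  out[grepl("^T\\.DP\\.Th", titles)] <- "DP69neg"
  out[grepl("^T\\.DP69\\+\\.Th", titles)] <- "DP69pos"
  out
}
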