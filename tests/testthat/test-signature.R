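# construct a population-mean expression matrix (3 replicates, no noise)
mean_matrix <- function(means) {
  # means: data.frame(gene, DN4, DP69neg, DP69pos)
  samples <- data.frame(
    sample_id = c(paste0("DN4_r", 1:3), paste0("DPn_r", 1:3),
                  paste0("DPp_r", 1:3)),
    population = rep(c("DN4", "DP69neg", "DP69pos"), each = 3))
  expr <- cbind(matrix(rep(means$DN4, 3), ncol = 3),
                matrix(rep(means$DP69neg, 3), ncol = 3),
                matrix(rep(means$DP69pos, 3), ncol = 3))
  dimnames(expr) <- list(means$gene, samples$sample_id)
  list(expr = expr, samples = samples)
}

test_that("dual-criteria filter admits the right genes with branch labels", {
  means <- data.frame(
    gene = c("hi1", "hi2", "hi3", "fc1", "fc2",
             "weak_lfc", "one_sided", "low_and_mild", "Rag1"),
    DN4      = c(400, 800, 1000, 10, 5, 500, 100, 50, 100),
    DP69neg  = c(1200, 2400, 2500, 60, 40, 900, 500, 150, 1500),
    DP69pos  = c(500, 900, 900, 12, 8, 480, 600, 60, 110))
  # hi1..hi3: lfc > 1 both ways, combined > 2000 but lfc < 2 somewhere
  # fc1, fc2: combined < 2000 but lfc > 2 both ways
  # weak_lfc: lfc < 1; one_sided: up vs DN4 only; low_and_mild: 1 < lfc < 2
  #   with combined < 2000; Rag1: would qualify but is excluded
  mm <- mean_matrix(means)
  sig <- derive_preselection_signature(mm$expr, mm$samples)
  expect_setequal(sig$gene, c("hi1", "hi2", "hi3", "fc1", "fc2"))
  expect_equal(sort(sig$gene[sig$branch == "expression"]),
               c("hi1", "hi2", "hi3"))
  expect_equal(sort(sig$gene[sig$branch == "fold_change"]), c("fc1", "fc2"))

  # all-equal matrix: zero fold changes, nothing admitted
  flat <- mean_matrix(data.frame(gene = paste0("g", 1:4), DN4 = 3000,
                                 DP69neg = 3000, DP69pos = 3000))
  expect_equal(nrow(derive_preselection_signature(flat$expr, flat$samples)), 0L)

  # missing population is a precondition error
  part <- mm$samples[mm$samples$population != "DP69pos", ]
  expect_error(
    derive_preselection_signature(mm$expr[, part$sample_id], part),
    "population")
})

test_that("signature filter is monotone in lfc_min", {
  set.seed(31)
  sim <- simulate_expression(expr_sim_params(
    n_genes = 400L, signature_genes = paste0("g", sprintf("%04d", 1:30)),
    signature_lfc = rep(c(1.2, 1.8, 2.6), each = 10), noise_sdlog = 0.3,
    seed = 31))
  sizes <- vapply(c(0.5, 1, 1.5, 2), function(th) {
    nrow(derive_preselection_signature(
      sim$expr, sim$samples,
      signature_criteria(lfc_min = th, lfc_strong = th + 1.5)))
  }, numeric(1L))
  expect_true(all(diff(sizes) <= 0))

  # every returned gene is attributed to an admitting branch
  sig <- derive_preselection_signature(sim$expr, sim$samples)
  expect_true(all(sig$branch %in% c("expression", "fold_change", "both")))
})

test_that("ion-channel filter applies expression and significance criteria", {
  # empty candidate list keeps only the always-include gene
  de0 <- data.frame(gene = character(0), stage = character(0),
                    padj = numeric(0), max_reads = numeric(0))
  expect_equal(filter_ion_channels(character(0), de0), "Tmie")

  # 4 of 10 candidates meet both criteria
  cand <- paste0("chan", 1:10)
  de <- rbind(
    data.frame(gene = cand, stage = "early",
               padj = c(0.01, 0.2, 0.03, 0.9, 0.04, 0.5, 0.01, 0.6, 0.7, 0.2),
               max_reads = c(100, 300, 15, 200, 50, 8, 90, 400, 2, 30)),
    data.frame(gene = cand, stage = "late",
               padj = c(0.8, 0.9, 0.2, 0.7, 0.6, 0.5, 0.9, 0.8, 0.9, 0.04),
               max_reads = c(100, 300, 15, 200, 50, 8, 90, 400, 2, 30)))
  # significant somewhere & >20 reads: chan1, chan5, chan7, chan10
  # chan3 significant but lowly expressed; chan2/4/8 expressed but not DE
  got <- filter_ion_channels(cand, de)
  expect_equal(got, sort(c("chan1", "chan5", "chan7", "chan10", "Tmie")))

  # expression matrix route gives the same answer
  expr <- matrix(rep(c(100, 300, 15, 200, 50, 8, 90, 400, 2, 30), 2),
                 ncol = 2, dimnames = list(cand, c("s1", "s2")))
  got2 <- filter_ion_channels(cand, de[, c("gene", "stage", "padj")],
                              expr = expr)
  expect_equal(got2, got)

  # candidates absent from the DE table warn and survive only via
  # always_include
  expect_warning(
    got3 <- filter_ion_channels(c(cand, "Tmie", "ghost"), de),
    "absent")
  expect_equal(got3, got)
})

test_that("scale_and_cluster z-scores rows and separates archetypes", {
  set.seed(32)
  # two well-separated row archetypes: early-peaking and late-peaking
  early <- matrix(rep(c(10, 8, 2, 1), each = 6), nrow = 6) +
    matrix(rnorm(24, 0, 0.1), nrow = 6)
  late <- matrix(rep(c(1, 2, 8, 10), each = 5), nrow = 5) +
    matrix(rnorm(20, 0, 0.1), nrow = 5)
  expr <- rbind(early, late)
  dimnames(expr) <- list(c(paste0("e", 1:6), paste0("l", 1:5)),
                         paste0("s", 1:4))
  res <- scale_and_cluster(expr, k = 2L)
  # each nonconstant row has mean 0 and sd 1
  expect_equal(unname(rowMeans(res$scaled)), rep(0, 11))
  expect_equal(unname(apply(res$scaled, 1, sd)), rep(1, 11))
  # perfect partition, numbered in developmental (column) order of the peak
  expect_equal(unname(res$clusters[paste0("e", 1:6)]), rep(1L, 6))
  expect_equal(unname(res$clusters[paste0("l", 1:5)]), rep(2L, 5))

  # k = number of rows -> every row its own cluster
  res_n <- scale_and_cluster(expr, k = nrow(expr))
  expect_equal(sort(unique(res_n$clusters)), seq_len(nrow(expr)))

  # row-order invariance (labels attach to the same genes)
  perm <- sample(nrow(expr))
  res_p <- scale_and_cluster(expr[perm, ], k = 2L)
  expect_equal(res_p$clusters[names(res$clusters)], res$clusters)

  # constant rows scale to zeros with a warning
  cexpr <- rbind(expr, const = rep(5, 4))
  expect_warning(res_c <- scale_and_cluster(cexpr, k = 2L), "constant")
  expect_equal(unname(res_c$scaled["const", ]), rep(0, 4))

  # replicate averaging collapses annotated sample groups
  expr2 <- cbind(expr, expr + matrix(rnorm(44, 0, 0.05), nrow = 11))
  colnames(expr2) <- paste0("s", 1:8)
  ann <- data.frame(sample_id = paste0("s", 1:8),
                    genotype = "wt", stage = rep(paste0("st", 1:4), 2))
  res_avg <- scale_and_cluster(expr2, ann, k = 2L)
  expect_equal(ncol(res_avg$scaled), 4L)
  expect_equal(res_avg$clusters[names(res$clusters)], res$clusters)
})

test_that("series-matrix reader + population mapping feed the filter", {
  fixture <- system.file("extdata", "synthetic_immgen_series_matrix.txt",
                         package = "thymotrack")
  expect_true(nzchar(fixture))
  geo <- read_geo_series_matrix(fixture)
  expect_equal(ncol(geo$expr), 9L)
  pops <- map_immgen_populations(geo$samples$title)
  expect_equal(sum(pops == "DN4", na.rm = TRUE), 3L)
  expect_equal(sum(pops == "DP69neg", na.rm = TRUE), 3L)
  expect_equal(sum(pops == "DP69pos", na.rm = TRUE), 3L)

  samples <- data.frame(sample_id = geo$samples$sample_id, population = pops)
  sig <- derive_preselection_signature(geo$expr, samples)
  # the fixture plants Themis-like high-expression genes and Slc6a19-like
  # strong-fold-change genes, plus decoys and Rag1/Rag2
  expect_setequal(sig$gene, c("Themis", "Clk3", "Slc6a19", "Wdr78"))
  expect_equal(sort(sig$gene[sig$branch == "expression"]),
               c("Clk3", "Themis"))
  expect_equal(sort(sig$gene[sig$branch == "fold_change"]),
               c("Slc6a19", "Wdr78"))

  # probe-to-gene collapsing averages mapped probes
  idm <- data.frame(id = rownames(geo$expr),
                    gene = sub("_p[12]$", "", rownames(geo$expr)))
  geo2 <- read_geo_series_matrix(fixture, id_map = idm)
  expect_false(anyDuplicated(rownames(geo2$expr)) > 0)
})
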