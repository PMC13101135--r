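# Readers/writers and preprocessing: round trips, missingness filtering,
# scaling, LD pruning, MAF filtering, feature stacking.

test_that("layer TSV round-trips, with empty cells as missing", {
  m <- matrix(c(1.5, NA, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("a1", "a2", "a3"), c("f1", "f2")))
  layer <- omics_layer("metabolome", m)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_layer_tsv(layer, path)
  back <- read_layer_tsv(path, "metabolome")
  expect_identical(back$data, m)
  expect_true(is.na(back$data["a2", "f1"]))

  # duplicated header id names the offender
  writeLines(c("accession\tf1\tf1", "a1\t1\t2"), path)
  expect_error(read_layer_tsv(path, "metabolome"), "f1")
})

test_that("constructors reject duplicate ids and bad dosages", {
  m <- matrix(0, 2, 2, dimnames = list(c("a", "a"), c("f1", "f2")))
  expect_error(omics_layer("genome", m), "duplicate accession")
  m2 <- matrix(3, 2, 2, dimnames = list(c("a", "b"), c("f1", "f2")))
  expect_error(omics_layer("genome", m2), "dosages")
})

test_that("VCF genotypes become dosages named CHROM-POS", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "Chr06\t15056895\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|1\t0/0",
    "Chr01\t100\t.\tC\tT\t.\tPASS\t.\tGT\t./.\t0/1\t1/1",
    "Chr02\t200\t.\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0"
  ), path)
  expect_message(layer <- read_genotypes_vcf(path), "multiallelic")
  expect_setequal(layer$feature_ids, c("Chr06-15056895", "Chr01-100"))
  expect_identical(unname(layer$data[, "Chr06-15056895"]), c(1, 2, 0))
  expect_true(is.na(layer$data["s1", "Chr01-100"]))
})

test_that("missingness filtering is feature-first, then accession", {
  g <- matrix(c(0, 1, 2, 1,
                1, NA, 0, 2,
                2, 2, 1, 0), 4, 3,
              dimnames = list(paste0("a", 1:4), c("Chr01-1", "Chr01-2", "Chr01-3")))
  ph <- matrix(c(1, 2, NA, 4, 5, 6, 7, 8), 4, 2,
               dimnames = list(paste0("a", 1:4), c("t1", "t2")))
  st <- omics_study("control", list(omics_layer("genome", g)), ph)
  out <- suppressMessages(filter_missing(st))
  # feature with the missing cell dropped first, then the accession with the
  # missing phenotype; traits are never dropped
  expect_setequal(out$layers$genome$feature_ids, c("Chr01-1", "Chr01-3"))
  expect_setequal(rownames(out$phenotypes), c("a1", "a2", "a4"))
  expect_identical(colnames(out$phenotypes), c("t1", "t2"))

  # fully observed studies pass through unchanged
  st2 <- omics_study("control",
                     list(omics_layer("genome", g[c(1, 2, 4), c(1, 3)])),
                     ph[c(1, 2, 4), ])
  expect_identical(filter_missing(st2)$layers$genome$data,
                   g[c(1, 2, 4), c(1, 3)])
})

test_that("scale_columns standardizes with divisor n and drops constants", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(-1, 0, 1))
  out <- suppressMessages(scale_columns(m))
  expect_equal(unname(out[, "a"]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_identical(attr(out, "dropped"), "b")
  expect_lt(max(abs(colMeans(out))), 1e-10)
  expect_lt(max(abs(colMeans(out^2) - 1)), 1e-10)
  # idempotence
  again <- scale_columns(out)
  expect_equal(as.numeric(again), as.numeric(out[, colnames(again)]),
               tolerance = 1e-12)
  expect_error(scale_columns(cbind(x = c(1, 1))), "zero variance")
})

test_that("LD pruning drops high-r^2 SNPs greedily and respects the window", {
  set.seed(8)
  base <- sample(0:2, 60, replace = TRUE)
  g <- cbind(`Chr01-100` = base, `Chr01-200` = base,
             `Chr01-300` = sample(0:2, 60, replace = TRUE))
  layer <- omics_layer("genome", matrix(g, 60, 3,
                                        dimnames = list(sprintf("a%02d", 1:60),
                                                        colnames(g))))
  kept <- ld_prune(layer, r2_threshold = 0.9, window = 10)
  expect_identical(kept, c("Chr01-100", "Chr01-300")) # duplicate dropped
  expect_identical(ld_prune(layer, r2_threshold = 1, window = 10),
                   colnames(g)) # vacuous threshold keeps all
  expect_error(ld_prune(layer, 0.5, window = 0), "window")

  # independent SNPs at large n survive a 0.95 threshold
  G <- simulate_genotypes(2000, 30, 30, c(0.1, 0.5), seed = 5)
  gl <- omics_layer("genome", G)
  expect_identical(sort(ld_prune(gl, 0.95, 100)), sort(colnames(G)))
  # retained pairs within the window never exceed the threshold
  r2 <- cor(G[, ld_prune(gl, 0.3, 100)])^2
  expect_true(all(r2[upper.tri(r2)] <= 0.3))
})

test_that("MAF filter keeps SNPs with MAF >= threshold (boundary inclusive)", {
  n <- 100
  col_f <- function(n_alt) c(rep(1, n_alt), rep(0, n - n_alt)) # dosage 0/1
  g <- cbind(`Chr01-1` = rep(0, n),       # f = 0 -> removed
             `Chr01-2` = col_f(9),        # f = 0.045 -> removed at 0.05
             `Chr01-3` = col_f(10),       # f = 0.050 -> retained (>=)
             `Chr01-4` = rep(1, n))       # f = 0.5 -> retained
  rownames(g) <- sprintf("a%03d", 1:n)
  out <- maf_filter(omics_layer("genome", g), 0.05)
  expect_setequal(out$feature_ids, c("Chr01-3", "Chr01-4"))
})

test_that("feature stacks concatenate layers in canonical order", {
  ps <- tiny_paired_study()
  st <- ps$control
  stack <- build_feature_stack(st)
  widths <- vapply(st$layers, function(l) ncol(l$data), integer(1))
  expect_identical(ncol(stack$matrix), sum(widths))
  expect_identical(unname(stack$layer_of[1]), "genome")
  expect_identical(unname(stack$layer_of[length(stack$layer_of)]), "microbiome")
  # layer_of partitions the feature universe exactly
  expect_identical(sort(names(stack$layer_of)), sort(stack$feature_ids))
  counts <- table(stack$layer_of)
  expect_identical(as.integer(counts[names(widths)]), unname(widths))
  # single-layer stack equals that layer
  s1 <- build_feature_stack(st, "metabolome")
  expect_identical(s1$matrix, st$layers$metabolome$data)
})

test_that("study directories round-trip", {
  ps <- tiny_paired_study()
  dir <- withr::local_tempdir()
  write_study_dir(ps$control, dir)
  back <- read_study_dir(dir)
  expect_identical(back$condition, "control")
  expect_equal(back$phenotypes, ps$control$phenotypes, tolerance = 1e-6)
  geno <- ps$control$layers$genome$data
  attr(geno, "block") <- NULL # simulation-side annotation, not part of the dialect
  expect_equal(back$layers$genome$data, geno, tolerance = 1e-12)
})
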