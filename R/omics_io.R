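# Data model, TSV/VCF readers and writers, and preprocessing:
# missingness filtering, column scaling, LD pruning, MAF filtering, and
# concatenation of omics layers into a single feature stack.

#' Omics layer container
#'
#' An accession x feature matrix plus its layer label. Genome layers must be
#' dosage-coded (0/1/2 or missing).
#'
#' @param name one of `"genome"`, `"metabolome"`, `"microbiome"`.
#' @param data numeric matrix with unique accession rownames and feature colnames.
#' @return an `omics_layer` object.
#' @export
omics_layer <- function(name, data) {
  name <- match.arg(name, c("genome", "metabolome", "microbiome"))
  if (!is.matrix(data)) data <- as.matrix(data)
  if (is.null(rownames(data)) || is.null(colnames(data))) {
    stop("layer matrix needs accession rownames and feature colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(data))) {
    stop("duplicate accession ids: ",
         paste(unique(rownames(data)[duplicated(rownames(data))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(data))) {
    stop("duplicate feature ids: ",
         paste(unique(colnames(data)[duplicated(colnames(data))]), collapse = ", "),
         call. = FALSE)
  }
  if (name == "genome") {
    vals <- data[!is.na(data)]
    if (length(vals) && !all(vals %in% c(0, 1, 2))) {
      stop("genome layer entries must be dosages in {0, 1, 2} or missing",
           call. = FALSE)
    }
  }
  structure(list(name = name, data = data,
                 feature_ids = colnames(data), accession_ids = rownames(data)),
            class = "omics_layer")
}

# Internal constructor for derived (e.g. scaled) layers where genome entries
# are no longer raw dosages; skips value checks but keeps the shape contract.
layer_unchecked <- function(name, data) {
  structure(list(name = name, data = data,
                 feature_ids = colnames(data), accession_ids = rownames(data)),
            class = "omics_layer")
}

#' @export
print.omics_layer <- function(x, ...) {
  cat(sprintf("<omics_layer '%s': %d accessions x %d features>\n",
              x$name, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' One condition's aligned multi-omics study
#'
#' @param condition `"control"` or `"drought"`.
#' @param layers named list of [omics_layer()] objects sharing accession ids.
#' @param phenotypes accession x trait matrix aligned with the layers.
#' @return an `omics_study` object.
#' @export
omics_study <- function(condition, layers, phenotypes) {
  condition <- match.arg(condition, c("control", "drought"))
  stopifnot(is.list(layers), length(layers) >= 1L)
  if (!is.matrix(phenotypes)) phenotypes <- as.matrix(phenotypes)
  acc <- rownames(phenotypes)
  if (is.null(acc) || is.null(colnames(phenotypes))) {
    stop("phenotypes need accession rownames and trait colnames", call. = FALSE)
  }
  for (l in layers) {
    stopifnot(inherits(l, "omics_layer"))
    if (!identical(l$accession_ids, acc)) {
      stop(sprintf("layer '%s' accession ids do not match phenotypes", l$name),
           call. = FALSE)
    }
  }
  names(layers) <- vapply(layers, `[[`, character(1), "name")
  structure(list(condition = condition, layers = layers,
                 phenotypes = phenotypes, trait_names = colnames(phenotypes)),
            class = "omics_study")
}

#' @export
print.omics_study <- function(x, ...) {
  cat(sprintf("<omics_study '%s': %d accessions, layers: %s, %d traits>\n",
              x$condition, nrow(x$phenotypes),
              paste(sprintf("%s(%d)", names(x$layers),
                            vapply(x$layers, function(l) ncol(l$data), integer(1))),
                    collapse = ", "),
              ncol(x$phenotypes)))
  invisible(x)
}

# TSV dialect: tab-separated, header row = feature ids, first column = accession
# id, empty cell = missing value.

#' Write / read an omics layer in the package's TSV dialect
#'
#' @param layer an [omics_layer()]; @param path file path.
#' @return `read_layer_tsv` returns an [omics_layer()]; `write_layer_tsv`
#'   returns `path` invisibly.
#' @export
write_layer_tsv <- function(layer, path) {
  stopifnot(inherits(layer, "omics_layer"))
  df <- data.frame(accession = layer$accession_ids, layer$data,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_layer_tsv
#' @param name layer label for the matrix read from `path`.
#' @export
read_layer_tsv <- function(path, name) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  feat <- header[-1]
  if (anyDuplicated(feat)) {
    stop("duplicate feature ids in header: ",
         paste(unique(feat[duplicated(feat)]), collapse = ", "), call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "",
                          colClasses = c("character", rep("numeric", length(feat))),
                          fill = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  omics_layer(name, m)
}

#' Read a genotype layer from a VCF file
#'
#' Biallelic SNP records become dosage columns (count of ALT alleles; missing
#' genotypes stay missing) named `"<CHROM>-<POS>"` with 1-based positions.
#' Multiallelic records are skipped with a message.
#'
#' @param path VCF file (plain or gzipped).
#' @return an [omics_layer()] with `name = "genome"`.
#' @export
read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    message(sum(multi), " multiallelic record(s) skipped")
  }
  keep <- which(!multi)
  if (length(keep) == 0L) stop("no usable biallelic records in ", path, call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  alleles <- function(g) {
    a <- strsplit(g, "[/|]")
    vapply(a, function(v) {
      if (length(v) == 0L || anyNA(v) || any(v %in% c(".", ""))) {
        return(NA_real_)
      }
      sum(v == "1")
    }, numeric(1))
  }
  dos <- t(apply(gt, 1, alleles))
  if (ncol(gt) == 1L) dos <- matrix(dos, ncol = 1L)
  ids <- paste0(fix[keep, "CHROM"], "-", fix[keep, "POS"])
  m <- t(dos)
  dimnames(m) <- list(colnames(gt), ids)
  omics_layer("genome", m)
}

#' Remove missing values from a study
#'
#' Feature-first filtering: omics-layer features containing any missing value
#' are dropped; accessions with any missing phenotype (traits are never
#' dropped) or any residual layer missingness are dropped second, keeping all
#' layers aligned. Dropped counts are reported per layer via `message()`.
#'
#' @param study an [omics_study()].
#' @return the filtered, fully observed [omics_study()].
#' @export
filter_missing <- function(study) {
  stopifnot(inherits(study, "omics_study"))
  layers <- lapply(study$layers, function(l) {
    bad <- colSums(is.na(l$data)) > 0
    if (any(bad)) {
      message(sprintf("layer '%s': dropped %d feature(s) with missing values",
                      l$name, sum(bad)))
    }
    kept <- l$data[, !bad, drop = FALSE]
    if (ncol(kept) == 0L) {
      stop(sprintf("layer '%s' has no features left after missingness filtering",
                   l$name), call. = FALSE)
    }
    omics_layer(l$name, kept)
  })
  bad_acc <- rowSums(is.na(study$phenotypes)) > 0
  for (l in layers) bad_acc <- bad_acc | rowSums(is.na(l$data)) > 0
  if (any(bad_acc)) {
    message(sprintf("dropped %d accession(s) with remaining missing values",
                    sum(bad_acc)))
  }
  if (all(bad_acc)) stop("no accessions left after missingness filtering", call. = FALSE)
  keep <- !bad_acc
  layers <- lapply(layers, function(l) omics_layer(l$name, l$data[keep, , drop = FALSE]))
  omics_study(study$condition, layers, study$phenotypes[keep, , drop = FALSE])
}

#' Standardize matrix columns to mean 0, variance 1 (divisor n)
#'
#' Zero-variance columns are dropped (their ids are reported via `message()`
#' and attached as `attr(, "dropped")`).
#'
#' @param m numeric matrix without missing values.
#' @return the standardized matrix.
#' @export
scale_columns <- function(m) {
  stopifnot(is.matrix(m), !anyNA(m))
  s <- col_sd_pop(m)
  zero <- s == 0
  if (all(zero)) stop("all columns have zero variance", call. = FALSE)
  if (any(zero)) {
    message("dropped zero-variance column(s): ",
            paste(colnames(m)[zero], collapse = ", "))
  }
  kept <- m[, !zero, drop = FALSE]
  out <- sweep(sweep(kept, 2, colMeans(kept)), 2, s[!zero], "/")
  attr(out, "dropped") <- colnames(m)[zero]
  out
}

# Parse "Chr-Pos" SNP ids into (chromosome, position) for genomic ordering.
parse_snp_ids <- function(ids) {
  pos <- sub(".*-", "", ids)
  chrom <- sub("-[^-]*$", "", ids)
  p <- suppressWarnings(as.numeric(pos))
  if (anyNA(p)) {
    stop("SNP ids must look like '<CHROM>-<POS>'; offending ids: ",
         paste(ids[is.na(p)][seq_len(min(3, sum(is.na(p))))], collapse = ", "),
         call. = FALSE)
  }
  data.frame(id = ids, chrom = chrom, pos = p, stringsAsFactors = FALSE)
}

#' Greedy windowed LD pruning
#'
#' SNPs are scanned left-to-right in genomic order (chromosome, then
#' position); a SNP is dropped if its squared Pearson correlation with any
#' already-retained SNP among the trailing `window` retained SNPs exceeds
#' `r2_threshold` (strict `>`, so `r2_threshold = 1` retains everything).
#' First-seen SNPs win ties.
#'
#' @param genome_layer an [omics_layer()] with complete dosages.
#' @param r2_threshold r^2 above which a SNP is considered redundant.
#' @param window number of trailing retained SNPs compared against (>= 1).
#' @return character vector of retained SNP ids, in genomic order.
#' @export
ld_prune <- function(genome_layer, r2_threshold, window = 100L) {
  stopifnot(inherits(genome_layer, "omics_layer"))
  if (anyNA(genome_layer$data)) stop("genotypes must be complete", call. = FALSE)
  assert_count(window, "window")
  info <- parse_snp_ids(genome_layer$feature_ids)
  ord <- order(info$chrom, info$pos)
  X <- genome_layer$data[, ord, drop = FALSE]
  kept <- integer(0)
  for (j in seq_len(ncol(X))) {
    recent <- kept[seq.int(max(1L, length(kept) - window + 1L),
                           length.out = min(window, length(kept)))]
    drop_it <- FALSE
    if (length(recent)) {
      r <- suppressWarnings(stats::cor(X[, j], X[, recent, drop = FALSE]))
      r[is.na(r)] <- 0
      drop_it <- any(r^2 > r2_threshold)
    }
    if (!drop_it) kept <- c(kept, j)
  }
  colnames(X)[kept]
}

#' Minor allele frequency filter
#'
#' Keeps SNPs with `min(f, 1 - f) >= maf_min`, where `f` is mean dosage / 2.
#'
#' @param genome_layer an [omics_layer()] with complete dosages.
#' @param maf_min MAF threshold (default 0.05).
#' @return the filtered [omics_layer()].
#' @export
maf_filter <- function(genome_layer, maf_min = 0.05) {
  stopifnot(inherits(genome_layer, "omics_layer"))
  if (anyNA(genome_layer$data)) stop("genotypes must be complete", call. = FALSE)
  f <- colMeans(genome_layer$data) / 2
  maf <- pmin(f, 1 - f)
  omics_layer("genome", genome_layer$data[, maf >= maf_min, drop = FALSE])
}

#' Concatenate scaled omics layers into one feature stack
#'
#' Columns are ordered genome, metabolome, microbiome (restricted to
#' `layers_to_use`); the `layer_of` map records each feature's source layer.
#'
#' @param study an [omics_study()] whose layers are aligned (and, for
#'   modeling, already scaled).
#' @param layers_to_use layer names to include, in any order.
#' @return a `feature_stack`: list with `matrix`, `feature_ids`, `layer_of`.
#' @export
build_feature_stack <- function(study,
                                layers_to_use = c("genome", "metabolome", "microbiome")) {
  stopifnot(inherits(study, "omics_study"))
  canonical <- c("genome", "metabolome", "microbiome")
  use <- canonical[canonical %in% layers_to_use]
  missing_layers <- setdiff(use, names(study$layers))
  if (length(missing_layers)) {
    stop("study lacks requested layer(s): ", paste(missing_layers, collapse = ", "),
         call. = FALSE)
  }
  acc <- rownames(study$phenotypes)
  blocks <- list()
  layer_of <- character(0)
  for (nm in use) {
    l <- study$layers[[nm]]
    if (!identical(l$accession_ids, acc)) {
      offenders <- c(setdiff(l$accession_ids, acc), setdiff(acc, l$accession_ids))
      stop(sprintf("layer '%s' accessions not aligned; offenders: %s", nm,
                   paste(utils::head(offenders, 5), collapse = ", ")), call. = FALSE)
    }
    blocks[[nm]] <- l$data
    layer_of <- c(layer_of, stats::setNames(rep(nm, ncol(l$data)), colnames(l$data)))
  }
  m <- do.call(cbind, blocks)
  colnames(m) <- names(layer_of)
  if (anyDuplicated(colnames(m))) {
    stop("duplicate feature ids across layers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(matrix = m, feature_ids = colnames(m), layer_of = layer_of),
            class = "feature_stack")
}

#' Write a study to a directory in the TSV dialect
#'
#' One TSV per layer plus `phenotypes.tsv`; layer metadata goes to a JSON
#' sidecar.
#'
#' @param study an [omics_study()]; @param dir output directory.
#' @return `dir` invisibly.
#' @export
write_study_dir <- function(study, dir) {
  stopifnot(inherits(study, "omics_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (l in study$layers) {
    write_layer_tsv(l, file.path(dir, paste0(l$name, ".tsv")))
  }
  df <- data.frame(accession = rownames(study$phenotypes), study$phenotypes,
                   check.names = FALSE)
  utils::write.table(df, file.path(dir, "phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  meta <- list(condition = study$condition,
               layers = lapply(study$layers, function(l) {
                 list(name = l$name, n_accessions = nrow(l$data),
                      n_features = ncol(l$data))
               }),
               trait_names = study$trait_names)
  jsonlite::write_json(meta, file.path(dir, "study.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a study directory written by [write_study_dir()]
#'
#' @param dir study directory.
#' @return an [omics_study()].
#' @export
read_study_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "study.json"), simplifyVector = TRUE)
  layer_names <- if (is.data.frame(meta$layers)) meta$layers$name else
    vapply(meta$layers, `[[`, character(1), "name")
  layers <- lapply(layer_names, function(nm) {
    read_layer_tsv(file.path(dir, paste0(nm, ".tsv")), nm)
  })
  pdf <- utils::read.delim(file.path(dir, "phenotypes.tsv"), check.names = FALSE,
                           na.strings = "")
  pheno <- as.matrix(pdf[, -1, drop = FALSE])
  rownames(pheno) <- pdf[[1]]
  omics_study(meta$condition, layers, pheno)
}
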