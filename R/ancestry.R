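# Supervised admixture-proportion estimation against labelled reference
# allele frequencies, and projection onto a precomputed PC space. The PCA
# space is consumed, never computed here: loadings are an input artifact.

#' Estimate admixture proportions for one individual
#'
#' Maximizes the supervised admixture log-likelihood
#' `sum_i [ x_i log p_i(q) + (2 - x_i) log(1 - p_i(q)) ]` with
#' `p_i(q) = sum_k q_k f_ik` over the probability simplex, where `x_i` is
#' the alternate-allele dosage and `f_ik` the reference frequency of variant
#' `i` in superpopulation `k`. The optimizer is an EM-style multiplicative
#' update (expected ancestry-of-origin allele counts); the log-likelihood is
#' concave in `q`, so a single uniform start converges to the global
#' optimum. Reference frequencies are clamped to `[1e-4, 1 - 1e-4]` to keep
#' the log-likelihood finite at fixed variants.
#'
#' @param dosages named numeric vector of dosages for one individual
#'   (names are variant keys `chrom:pos:ref:alt`); `NA` entries are dropped.
#' @param ref a `ref_frequencies` object.
#' @param min_overlap minimum number of overlapping variants (default 100).
#' @param tol convergence threshold on the log-likelihood gain.
#' @param max_iter maximum EM iterations.
#' @return an `ancestry_profile`: list with `proportions` (named, on the
#'   simplex), `loglik`, `n_variants`, `converged`, `identifiable`.
#' @export
estimate_admixture <- function(dosages, ref, min_overlap = 100L,
                               tol = 1e-8, max_iter = 5000L) {
  stopifnot(inherits(ref, "ref_frequencies"))
  keys <- rownames(ref$freq)
  use <- intersect(names(dosages)[!is.na(dosages)], keys)
  stop_if(length(use) < min_overlap,
          sprintf("only %d overlapping variants (< %d required)",
                  length(use), min_overlap))
  x <- as.numeric(dosages[use])
  f <- clamp(ref$freq[use, , drop = FALSE], 1e-4, 1 - 1e-4)
  K <- ncol(f)
  labels <- colnames(f)
  # flat likelihood: identical frequencies across ancestries
  if (max(apply(f, 1, function(r) diff(range(r)))) < 1e-12) {
    warning("reference frequencies identical across ancestries; ",
            "admixture proportions are not identifiable", call. = FALSE)
    q <- stats::setNames(rep(1 / K, K), labels)
    p <- drop(f %*% q)
    ll <- sum(x * log(p) + (2 - x) * log(1 - p))
    return(structure(list(proportions = q, loglik = ll,
                          n_variants = length(x), converged = TRUE,
                          identifiable = FALSE),
                     class = "ancestry_profile"))
  }
  q <- rep(1 / K, K)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p <- drop(f %*% q)
    ll <- sum(x * log(p) + (2 - x) * log(1 - p))
    if (ll - ll_old < tol && it > 1L) { converged <- TRUE; break }
    ll_old <- ll
    # expected ancestry-of-origin counts for alt and ref alleles
    A <- q * drop(crossprod(f, x / p))
    B <- q * drop(crossprod(1 - f, (2 - x) / (1 - p)))
    q <- (A + B) / (2 * length(x))
    q <- q / sum(q)   # guard tiny numerical drift off the simplex
  }
  q[q < 1e-12] <- 0
  q <- q / sum(q)
  structure(list(proportions = stats::setNames(q, labels), loglik = ll,
                 n_variants = length(x), converged = converged,
                 identifiable = TRUE),
            class = "ancestry_profile")
}

#' @export
print.ancestry_profile <- function(x, ...) {
  cat("<ancestry_profile>",
      paste(sprintf("%s=%.3f", names(x$proportions), x$proportions),
            collapse = " "),
      sprintf("(loglik %.2f, %d variants)\n", x$loglik, x$n_variants))
  invisible(x)
}

#' Estimate admixture proportions for a cohort
#'
#' Applies [estimate_admixture()] to each row of a dosage matrix.
#'
#' @param genotypes a [dosage_matrix()].
#' @param ref a `ref_frequencies` object.
#' @param ... passed to [estimate_admixture()].
#' @return matrix of proportions (individuals x ancestries) with attribute
#'   `"loglik"`.
#' @export
estimate_admixture_cohort <- function(genotypes, ref, ...) {
  stopifnot(inherits(genotypes, "dosage_matrix"))
  res <- lapply(genotypes$ids, function(id) {
    estimate_admixture(genotypes$dosages[id, ], ref, ...)
  })
  q <- do.call(rbind, lapply(res, function(r) r$proportions))
  rownames(q) <- genotypes$ids
  attr(q, "loglik") <- vapply(res, function(r) r$loglik, numeric(1))
  q
}

#' Map admixture proportions to a major-ancestry label
#'
#' The label is the argmax ancestry, provided its proportion reaches
#' `threshold`; otherwise `"admixed"`.
#'
#' @param proportions matrix (individuals x ancestries) or a single named
#'   vector.
#' @param threshold minimum proportion for a definite label (default 0,
#'   i.e. plain argmax).
#' @return character vector of labels.
#' @export
major_ancestry <- function(proportions, threshold = 0) {
  if (is.null(dim(proportions))) proportions <- t(as.matrix(proportions))
  lab <- colnames(proportions)[max.col(proportions, ties.method = "first")]
  top <- apply(proportions, 1, max)
  lab[top < threshold] <- "admixed"
  lab
}

#' PC loadings for projection onto a precomputed PCA space
#'
#' @param variants data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param center per-variant centering means (mean dosage in the reference).
#' @param loadings matrix (variants x PCs) of loadings.
#' @return object of class `pc_loadings`.
#' @export
pc_loadings <- function(variants, center, loadings) {
  loadings <- as.matrix(loadings)
  stop_if(nrow(loadings) != nrow(variants) ||
            length(center) != nrow(variants),
          "variants, center and loadings must align")
  stop_if(any(!is.finite(loadings)), "loadings must be finite")
  stop_if(ncol(loadings) < 1, "at least one PC required")
  if (is.null(colnames(loadings)))
    colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  rownames(loadings) <- variant_key(variants$chrom, variants$pos,
                                    variants$ref, variants$alt)
  structure(list(variants = as.data.frame(variants),
                 center = stats::setNames(center, rownames(loadings)),
                 loadings = loadings),
            class = "pc_loadings")
}

#' Read PC loadings from TSV (chrom, pos, ref, alt, center, PC1..PCl)
#' @param path TSV path.
#' @return a [pc_loadings()].
#' @export
read_pc_loadings_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  keycols <- c("chrom", "pos", "ref", "alt", "center")
  stop_if(!all(keycols %in% names(tab)), path,
          ": needs columns chrom, pos, ref, alt, center")
  pcs <- setdiff(names(tab), keycols)
  pc_loadings(tab[, c("chrom", "pos", "ref", "alt")], tab$center,
              as.matrix(tab[, pcs, drop = FALSE]))
}

#' Write PC loadings as TSV
#' @param loadings a [pc_loadings()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pc_loadings_tsv <- function(loadings, path) {
  tab <- cbind(loadings$variants, center = unname(loadings$center),
               as.data.frame(loadings$loadings, row.names = NULL))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Project genotypes onto precomputed principal components
#'
#' `coordinate_j = sum_i (x_i - mean_i) * loading_ij` over the variants
#' shared between the genotypes and the loadings; missing dosages are
#' imputed at the centering mean (zero contribution).
#'
#' @param genotypes a [dosage_matrix()] or a single named dosage vector.
#' @param loadings a [pc_loadings()].
#' @param min_overlap minimum shared variants (default 1).
#' @return matrix of PC coordinates (individuals x PCs).
#' @export
project_pca <- function(genotypes, loadings, min_overlap = 1L) {
  stopifnot(inherits(loadings, "pc_loadings"))
  if (inherits(genotypes, "dosage_matrix")) {
    x <- genotypes$dosages
  } else {
    x <- t(as.matrix(genotypes))
    rownames(x) <- "individual"
  }
  use <- intersect(colnames(x), rownames(loadings$loadings))
  stop_if(length(use) < min_overlap,
          sprintf("only %d variants overlap the loadings (< %d)",
                  length(use), min_overlap))
  xc <- sweep(x[, use, drop = FALSE], 2, loadings$center[use])
  xc[is.na(xc)] <- 0   # missing dosage imputed at the centering mean
  xc %*% loadings$loadings[use, , drop = FALSE]
}
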