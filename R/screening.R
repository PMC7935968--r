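## Multivariate screening stage: standardization, iterative-PCA imputation
## of missing entries, standardized PCA, and k-means on the first two
## components, with per-cluster summaries.

.screenData <- function(x) {
    if (methods::is(x, "ScreeningMatrix")) x@data else as.matrix(x)
}

#' Column-standardize a screening matrix
#'
#' (x - mean) / sd per column, computed on the observed (non-missing)
#' entries. Constant columns cannot be standardized and are rejected by
#' name.
#'
#' @param x a [ScreeningMatrix-class] or numeric matrix.
#' @return A numeric matrix of the same shape (NAs preserved).
#' @export
standardizeScreening <- function(x) {
    m <- .screenData(x)
    sds <- apply(m, 2, stats::sd, na.rm = TRUE)
    bad <- which(is.na(sds) | sds == 0)
    if (length(bad))
        stop("zero-variance column(s): ",
             paste(colnames(m)[bad], collapse = ", "))
    scale(m, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' Impute missing entries by iterative PCA
#'
#' The EM-style iterative-PCA scheme for missing data: initialize missing
#' cells with column means, then alternate a rank-`ncomp` reconstruction
#' (column-centred truncated SVD) with re-substitution of the
#' reconstruction into the missing cells, until the imputed cells change by
#' less than `tol` (RMS) or `maxIter` is reached. Observed entries are
#' never altered. On an exactly rank-`ncomp` matrix the imputed cells
#' converge to the true values.
#'
#' By default the reconstruction is regularized: singular values are
#' shrunk by the residual variance estimated from the trailing components,
#' which damps noise-dominated directions. Without it the fixed-point
#' iteration can crawl (and overfit) when the `ncomp`-th eigenvalue sits in
#' the noise floor; with an exactly low-rank matrix the residual variance
#' is nil and the shrinkage vanishes, so exact recovery is unaffected.
#'
#' @param x a [ScreeningMatrix-class] or numeric matrix with NAs.
#' @param ncomp reconstruction rank, < min(dim); default 2 to match the
#'   downstream use of two components.
#' @param tol convergence tolerance on the imputed cells (RMS change per
#'   iteration).
#' @param maxIter iteration cap; non-convergence yields a warning and the
#'   best iterate.
#' @param regularized shrink singular values by the estimated residual
#'   variance (default TRUE).
#' @return The completed numeric matrix, with attribute `"imputation"`:
#'   list(iterations, converged, nImputed).
#' @export
imputeIterativePCA <- function(x, ncomp = 2, tol = 1e-9, maxIter = 5000,
                               regularized = TRUE) {
    m <- .screenData(x)
    if (ncomp >= min(dim(m)))
        stop("ncomp must be smaller than both matrix dimensions")
    miss <- is.na(m)
    if (any(colSums(!miss) == 0))
        stop("column(s) with no observed entries cannot be imputed: ",
             paste(which(colSums(!miss) == 0), collapse = ", "))
    if (!any(miss)) {
        attr(m, "imputation") <- list(iterations = 0L, converged = TRUE,
                                      nImputed = 0L)
        return(m)
    }
    colMeansObs <- colMeans(m, na.rm = TRUE)
    filled <- m
    filled[miss] <- colMeansObs[col(m)[miss]]
    n <- nrow(m)
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        mu <- colMeans(filled)
        centred <- sweep(filled, 2, mu)
        sv <- svd(centred)
        lambda <- sv$d^2 / (n - 1)
        sigma2 <- if (regularized && length(lambda) > ncomp)
            mean(lambda[(ncomp + 1):length(lambda)]) else 0
        dShrunk <- pmax(0, sv$d[seq_len(ncomp)]^2 - (n - 1) * sigma2) /
            sv$d[seq_len(ncomp)]
        recon <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
            (diag(dShrunk, ncomp) %*%
             t(sv$v[, seq_len(ncomp), drop = FALSE]))
        recon <- sweep(recon, 2, mu, `+`)
        delta <- sqrt(mean((recon[miss] - filled[miss])^2))
        filled[miss] <- recon[miss]
        if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
        warning("iterative PCA imputation did not converge in ",
                maxIter, " iterations; returning the last iterate")
    attr(filled, "imputation") <- list(iterations = iter,
                                       converged = converged,
                                       nImputed = sum(miss))
    filled
}

#' Principal component analysis of a standardized screening matrix
#'
#' Standard PCA (singular value decomposition of the column-centred
#' matrix) with a deterministic sign convention: within each component the
#' largest-magnitude loading is made positive, so scores are reproducible
#' across platforms.
#'
#' @param x a complete numeric matrix (standardize first for the
#'   correlation-structure PCA the screening stage uses).
#' @return list(scores, loadings, varianceFraction).
#' @export
screenPCA <- function(x) {
    m <- .screenData(x)
    if (nrow(m) < 3) stop("PCA needs at least 3 observations")
    if (anyNA(m)) stop("PCA input must be complete; impute first")
    pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
    pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
    pc$x <- sweep(pc$x, 2, flip, `*`)
    list(scores = pc$x, loadings = pc$rotation,
         varianceFraction = pc$sdev^2 / sum(pc$sdev^2))
}

#' k-means clustering on the first two principal components
#'
#' Lloyd's algorithm (via [stats::kmeans()]) on PC1-PC2 with `nInit` seeded
#' restarts, keeping the solution with the lowest within-cluster sum of
#' squares. Reports between_SS / total_SS as a percentage — the standard
#' k-means quality line.
#'
#' @param scores score matrix from [screenPCA()] (>= 2 columns).
#' @param k number of clusters (default 4).
#' @param seed integer seed making the restarts reproducible.
#' @param nInit number of random restarts.
#' @return A [ClusterResult-class].
#' @export
kmeansPC12 <- function(scores, k = 4, seed = 1, nInit = 25) {
    pts <- scores[, seq_len(min(2, ncol(scores))), drop = FALSE]
    uniq <- unique(pts)
    nDistinct <- nrow(uniq)
    if (k > nDistinct)
        stop("k exceeds the number of distinct points")
    if (k == nDistinct) {
        # every distinct point is its own centroid: within-SS is zero
        labels <- match(apply(pts, 1, paste, collapse = "\r"),
                        apply(uniq, 1, paste, collapse = "\r"))
        return(new("ClusterResult", labels = as.integer(labels),
                   centroids = uniq, betweenSSPct = 100,
                   pcVarFrac = numeric(0), imputation = list()))
    }
    set.seed(seed)
    km <- stats::kmeans(pts, centers = k, nstart = nInit, iter.max = 100)
    new("ClusterResult",
        labels = as.integer(km$cluster),
        centroids = km$centers,
        betweenSSPct = 100 * km$betweenss / km$totss,
        pcVarFrac = numeric(0),
        imputation = list())
}

#' Screening pipeline: impute, standardize, PCA, k-means
#'
#' The full multivariate stage in one call, mirroring how a screening
#' matrix is analysed in practice: iterative-PCA imputation of missing
#' values, column standardization, PCA, and k-means on the first two
#' components.
#'
#' @param x a [ScreeningMatrix-class] or numeric matrix (NAs allowed).
#' @param k number of clusters.
#' @param seed integer seed.
#' @param ncomp imputation rank.
#' @param nInit k-means restarts.
#' @return A [ClusterResult-class] with `pcVarFrac` and the imputation
#'   report filled in.
#' @export
screenCluster <- function(x, k = 4, seed = 1, ncomp = 2, nInit = 25) {
    completed <- imputeIterativePCA(x, ncomp = ncomp)
    rep <- attr(completed, "imputation")
    std <- standardizeScreening(completed)
    pc <- screenPCA(std)
    res <- kmeansPC12(pc$scores, k = k, seed = seed, nInit = nInit)
    res@pcVarFrac <- pc$varianceFraction
    res@imputation <- rep
    methods::validObject(res)
    res
}

#' Per-cluster summary of a screening matrix
#'
#' Medians of every numeric variable and counts of every metadata category
#' per cluster — the tidy-table replacement for biplot/heatmap inspection.
#' Empty clusters (possible after Lloyd's algorithm) are emitted with zero
#' counts, not dropped.
#'
#' @param result a [ClusterResult-class].
#' @param x the clustered [ScreeningMatrix-class].
#' @return A data.frame, one row per cluster.
#' @export
clusterSummary <- function(result, x) {
    m <- .screenData(x)
    meta <- if (methods::is(x, "ScreeningMatrix")) x@rowData else NULL
    if (length(result@labels) != nrow(m))
        stop("labels do not align with the matrix rows")
    k <- nrow(result@centroids)
    rows <- lapply(seq_len(k), function(cl) {
        sel <- result@labels == cl
        med <- if (any(sel)) {
            apply(m[sel, , drop = FALSE], 2, stats::median, na.rm = TRUE)
        } else {
            stats::setNames(rep(NA_real_, ncol(m)), colnames(m))
        }
        out <- data.frame(cluster = cl, n = sum(sel), t(med))
        if (!is.null(meta)) {
            for (col in names(meta)) {
                if (is.character(meta[[col]]) || is.factor(meta[[col]])) {
                    tab <- table(meta[[col]][sel])
                    out[[paste0(col, "_top")]] <-
                        if (length(tab)) names(tab)[which.max(tab)] else NA
                }
            }
        }
        out
    })
    do.call(rbind, rows)
}
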