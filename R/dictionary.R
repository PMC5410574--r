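#' @include AllClasses.R
NULL

#' PCA denoising of event windows
#'
#' Projects the windows onto the minimal number of leading principal
#' components whose cumulative explained variance reaches
#' \code{varianceTarget} (98\% in the standard pipeline) and reconstructs
#' them from those components only, removing high-frequency variation while
#' preserving the event shapes.
#'
#' @param windows events-by-samples numeric matrix (>= 2 rows).
#' @param varianceTarget cumulative variance fraction in (0, 1].
#' @return list with \code{basis} (a \code{\link{PcaBasis}}) and
#'   \code{windows} (the reconstructed matrix, same shape as the input).
#' @export
pcaReduce <- function(windows, varianceTarget = 0.98) {
  windows <- as.matrix(windows)
  if (nrow(windows) < 2)
    stop("invalid argument: at least 2 windows required")
  if (varianceTarget <= 0 || varianceTarget > 1)
    stop("invalid argument: varianceTarget must be in (0, 1]")
  pc <- prcomp(windows, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  ratios <- v / sum(v)
  nsel <- which(cumsum(ratios) >= varianceTarget - 1e-12)[1]
  if (is.na(nsel)) nsel <- length(ratios)
  comp <- pc$rotation[, seq_len(nsel), drop = FALSE]
  recon <- pc$x[, seq_len(nsel), drop = FALSE] %*% t(comp)
  recon <- sweep(recon, 2, pc$center, "+")
  basis <- new("PcaBasis", components = comp, center = pc$center,
               explainedRatios = ratios, nSelected = as.integer(nsel),
               varianceTarget = varianceTarget)
  list(basis = basis, windows = recon)
}

#' Project new windows onto a stored PCA basis
#'
#' @param basis a \code{\link{PcaBasis}}.
#' @param windows matrix (or single vector) of windows.
#' @return reconstructed windows in the denoised representation.
#' @export
reconstructWindows <- function(basis, windows) {
  windows <- rbind(windows)
  centred <- sweep(windows, 2, basis@center)
  recon <- centred %*% basis@components %*% t(basis@components)
  sweep(recon, 2, basis@center, "+")
}

# k-means with Ward-linkage initialization: random restarts alone often land
# in poor local optima when well-separated clusters have very unequal sizes,
# so we seed one run from a Ward-tree cut and keep the best inertia.
.kmeansFit <- function(windows, k, nstart = 10, D = NULL) {
  if (k == nrow(windows))  # one point per cluster: the fit is exact
    return(list(cluster = seq_len(k), centers = windows, tot.withinss = 0))
  if (is.null(D)) D <- dist(windows)
  hc <- stats::hclust(D, method = "ward.D2")
  cut <- stats::cutree(hc, k)
  centers0 <- sweep(rowsum(windows, cut), 1, tabulate(cut), "/")
  km <- kmeans(windows, centers0, iter.max = 100)
  km2 <- suppressWarnings(kmeans(windows, k, nstart = nstart, iter.max = 100))
  if (km2$tot.withinss < km$tot.withinss) km2 else km
}

.chIndex <- function(windows, cluster) {
  n <- nrow(windows)
  k <- length(unique(cluster))
  if (k < 2) return(-Inf)
  g <- colMeans(windows)
  within <- 0; between <- 0
  for (cl in unique(cluster)) {
    w <- windows[cluster == cl, , drop = FALSE]
    c0 <- colMeans(w)
    within <- within + sum(sweep(w, 2, c0)^2)
    between <- between + nrow(w) * sum((c0 - g)^2)
  }
  (between / (k - 1)) / (within / (n - k))
}

#' Choose the dictionary size by internal-validity consensus
#'
#' Fits k-means for every candidate k and scores each partition with two
#' internal validity indices (average silhouette width and the
#' Calinski-Harabasz criterion). Each index votes for its best k; the
#' consensus is the modal vote, with ties resolved toward the smaller k
#' (parsimony). When even the best average silhouette stays below 0.25 the
#' data show no substantial cluster structure and the minimum candidate is
#' returned with a message.
#'
#' @param windows events-by-samples matrix.
#' @param kCandidates integer candidates within [2, nrow(windows) - 1].
#' @param seed optional integer seed (k-means uses 10 restarts per k).
#' @return the selected k.
#' @export
chooseK <- function(windows, kCandidates = 2:15, seed = NULL) {
  windows <- as.matrix(windows)
  kCandidates <- sort(unique(as.integer(kCandidates)))
  if (!length(kCandidates)) stop("invalid argument: empty candidate range")
  if (min(kCandidates) < 2 || max(kCandidates) > nrow(windows) - 1)
    stop("invalid argument: kCandidates must lie in [2, n - 1]")
  if (!is.null(seed)) set.seed(seed)
  D <- dist(windows)
  sil <- ch <- rep(NA_real_, length(kCandidates))
  for (i in seq_along(kCandidates)) {
    km <- .kmeansFit(windows, kCandidates[i], D = D)
    sil[i] <- mean(cluster::silhouette(km$cluster, D)[, "sil_width"])
    ch[i] <- .chIndex(windows, km$cluster)
  }
  if (max(sil) < 0.25) {
    message("chooseK: no substantial cluster structure (max silhouette ",
            sprintf("%.2f", max(sil)), "); returning the minimum candidate")
    return(min(kCandidates))
  }
  votes <- c(kCandidates[which.max(sil)], kCandidates[which.max(ch)])
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}

#' Fit a shape dictionary by k-means
#'
#' Prototypes are cluster centroids of the (typically PCA-denoised) event
#' windows; per-cluster dispersion is the per-sample standard deviation
#' around the centroid. Clusters are relabeled deterministically (decreasing
#' size, then centroid energy) as "A", "B", ... so the same seed always
#' yields the same dictionary. k-means runs once from a Ward-linkage tree
#' cut and 10 times from random starts, keeping the
#' best inertia.
#'
#' @param windows events-by-samples matrix.
#' @param k number of prototypes, 1 <= k <= nrow(windows).
#' @param seed optional integer seed.
#' @param pca optional \code{\link{PcaBasis}} recorded in the dictionary so
#'   future events can be projected the same way before labeling.
#' @return a \code{\link{ShapeDictionary}}.
#' @export
fitDictionary <- function(windows, k, seed = NULL, pca = NULL) {
  windows <- as.matrix(windows)
  if (k < 1 || k > nrow(windows))
    stop("invalid argument: k must lie in [1, number of windows]")
  if (!is.null(seed)) set.seed(seed)
  if (k == 1) {
    centers <- matrix(colMeans(windows), 1)
    clus <- rep(1L, nrow(windows))
  } else {
    km <- .kmeansFit(windows, k)
    centers <- km$centers
    clus <- km$cluster
  }
  size <- tabulate(clus, nbins = k)
  energy <- rowSums(centers^2)
  ord <- order(-size, -energy)
  centers <- centers[ord, , drop = FALSE]
  disp <- matrix(0, k, ncol(windows))
  for (j in seq_len(k)) {
    w <- windows[clus == ord[j], , drop = FALSE]
    if (nrow(w) > 1) disp[j, ] <- apply(w, 2, sd)
  }
  labels <- LETTERS[seq_len(k)]
  centers <- unname(centers)
  rownames(centers) <- labels
  new("ShapeDictionary", prototypes = centers, labels = labels,
      dispersions = disp, pca = pca)
}

#' Label event windows by nearest prototype
#'
#' Each window receives the label of the Euclidean-closest prototype; exact
#' ties go to the lowest-index label. When the dictionary carries a PCA
#' basis the windows are projected onto it first, so labeling operates in
#' the same denoised representation the dictionary was fit in.
#'
#' @param windows matrix of processed windows (or a single window vector).
#' @param dictionary a \code{\link{ShapeDictionary}}.
#' @return character vector of labels, one per window.
#' @export
labelEvents <- function(windows, dictionary) {
  stopifnot(is(dictionary, "ShapeDictionary"))
  windows <- rbind(windows)
  P <- dictionary@prototypes
  if (ncol(windows) != ncol(P))
    stop("invalid argument: window length does not match prototypes")
  if (!is.null(dictionary@pca))
    windows <- reconstructWindows(dictionary@pca, windows)
  # squared distances via the expansion |w - p|^2 = |w|^2 - 2 w.p + |p|^2
  cross <- windows %*% t(P)
  d2 <- sweep(-2 * cross, 2, rowSums(P^2), "+")
  best <- max.col(-d2, ties.method = "first")
  dictionary@labels[best]
}

#' Build a dictionary from detected events
#'
#' Convenience wrapper chaining \code{\link{pcaReduce}},
#' \code{\link{chooseK}} (unless \code{forcedK} is given) and
#' \code{\link{fitDictionary}} on the denoised windows.
#'
#' @param events a preprocessed \code{\link{CdpEventSet}} or a windows
#'   matrix.
#' @param varianceTarget PCA cumulative-variance target.
#' @param kCandidates candidate dictionary sizes for \code{\link{chooseK}}.
#' @param forcedK optional fixed dictionary size (bypasses selection).
#' @param seed optional integer seed.
#' @return a \code{\link{ShapeDictionary}} carrying the PCA basis.
#' @export
buildDictionary <- function(events, varianceTarget = 0.98,
                            kCandidates = 2:15, forcedK = NULL, seed = NULL) {
  windows <- if (is(events, "CdpEventSet")) events@processedWindows
             else as.matrix(events)
  red <- pcaReduce(windows, varianceTarget)
  k <- if (is.null(forcedK)) {
    kc <- kCandidates[kCandidates >= 2 & kCandidates <= nrow(windows) - 1]
    chooseK(red$windows, kc, seed = seed)
  } else forcedK
  fitDictionary(red$windows, k, seed = seed, pca = red$basis)
}
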