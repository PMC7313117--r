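# Trip-level tactic classification: behaviour-composition profiles, cluster
# number selection by index consensus, and k-means mapping to static (SF)
# versus dynamic (DF) foraging.

#' Behaviour composition of a trip
#'
#' Proportion of (smoothed) behavioural labels within a trip, in the fixed
#' order perch, intensive search, extensive search, relocation.
#'
#' @param mode Character vector of per-fix behavioural labels (one trip).
#' @return Named numeric vector of four proportions summing to 1.
#' @export
trip_profile <- function(mode) {
  mode <- mode[!is.na(mode)]
  if (length(mode) == 0) stop("trip_profile() needs at least one labelled fix", call. = FALSE)
  bad <- setdiff(unique(mode), BEHAVIOUR_MODES)
  if (length(bad)) stop("unknown behaviour label: ", paste(bad, collapse = ", "), call. = FALSE)
  lv <- c("perch", "intensive_search", "extensive_search", "relocation")
  tab <- table(factor(mode, levels = lv))
  stats::setNames(as.numeric(tab) / length(mode), lv)
}

total_withinss <- function(x, k, nstart = 10, iter_max = 50) {
  if (k == 1) return(sum(scale(x, scale = FALSE)^2))
  stats::kmeans(x, k, nstart = nstart, iter.max = iter_max)$tot.withinss
}

calinski_harabasz <- function(x, km) {
  n <- nrow(x); k <- nrow(km$centers)
  b <- km$totss - km$tot.withinss
  (b / (k - 1)) / (km$tot.withinss / (n - k))
}

davies_bouldin <- function(x, km) {
  k <- nrow(km$centers)
  s <- vapply(1:k, function(j) {
    pts <- x[km$cluster == j, , drop = FALSE]
    if (nrow(pts) == 0) return(0)
    mean(sqrt(rowSums((pts - matrix(km$centers[j, ], nrow(pts), ncol(x),
                                    byrow = TRUE))^2)))
  }, numeric(1))
  d <- as.matrix(stats::dist(km$centers))
  r <- outer(s, s, "+") / pmax(d, .Machine$double.eps)
  diag(r) <- -Inf
  mean(apply(r, 1, max))
}

#' Select the number of trip clusters by index consensus
#'
#' Five indices vote for the number of clusters of the trip-profile cloud:
#' the gap statistic (Tibshirani 1-SE rule, the only index in the set able to
#' support "no clustering", k = 1), mean silhouette width, Calinski-Harabasz,
#' Davies-Bouldin and the Hartigan rule (smallest k with
#' `(W_k/W_{k+1} - 1)(n - k - 1) <= 10`). Consensus is two-stage: if the gap
#' statistic supports no clustering the answer is k = 1; otherwise the
#' majority vote wins, with ties broken toward smaller k.
#'
#' @param profiles Matrix or data frame of trip profiles (rows = trips).
#' @param k_range Candidate cluster numbers (shrunk with a warning when there
#'   are fewer profiles than `max(k_range)`).
#' @param B Number of reference-set bootstraps for the gap statistic.
#' @param seed Integer seed for the k-means restarts and gap references.
#' @return A list with `k` (the consensus), `votes` (per-index choices) and
#'   the gap-statistic table.
#' @export
select_k <- function(profiles, k_range = 1:8, B = 50, seed = 1) {
  x <- as.matrix(profiles)
  n <- nrow(x)
  if (n < 10) stop("select_k() needs at least 10 profiles", call. = FALSE)
  if (n <= max(k_range)) {
    warning("fewer profiles than max(k_range): shrinking the candidate range")
    k_range <- k_range[k_range < n]
  }
  kmax <- max(k_range)
  with_rng(seed, {
    gap <- cluster::clusGap(x, FUNcluster = function(xx, k) {
      stats::kmeans(xx, k, nstart = 10, iter.max = 50)
    }, K.max = kmax, B = B, verbose = FALSE)
    k_gap <- cluster::maxSE(gap$Tab[, "gap"], gap$Tab[, "SE.sim"],
                            method = "Tibs2001SEmax")

    km <- lapply(2:kmax, function(k) stats::kmeans(x, k, nstart = 10, iter.max = 50))
    names(km) <- 2:kmax
    w <- c(total_withinss(x, 1), vapply(km, `[[`, numeric(1), "tot.withinss"))

    dmat <- stats::dist(x)
    sil <- vapply(km, function(f) {
      mean(cluster::silhouette(f$cluster, dmat)[, "sil_width"])
    }, numeric(1))
    ch <- vapply(km, function(f) calinski_harabasz(x, f), numeric(1))
    db <- vapply(km, function(f) davies_bouldin(x, f), numeric(1))

    hart <- (w[-length(w)] / w[-1] - 1) * (n - seq_len(kmax - 1) - 1)
    k_hart <- if (any(hart <= 10)) which(hart <= 10)[1] else kmax

    votes <- c(gap = as.integer(k_gap),
               silhouette = as.integer(names(which.max(sil))),
               calinski_harabasz = as.integer(names(which.max(ch))),
               davies_bouldin = as.integer(names(which.min(db))),
               hartigan = as.integer(k_hart))

    k_star <- if (votes["gap"] == 1L) {
      1L
    } else {
      tab <- table(votes)
      winners <- as.integer(names(tab[tab == max(tab)]))
      min(winners)
    }
    list(k = k_star, votes = votes, gap = gap$Tab)
  })
}

#' K-means tactic assignment of trip profiles
#'
#' Best-of-restarts Lloyd k-means on the four-proportion trip profiles. With
#' `k = 2` the cluster whose centroid has the higher perching proportion is
#' labelled static foraging (SF) and the other dynamic foraging (DF),
#' matching the field interpretation of perch-dominated versus
#' flight-search-dominated trips.
#'
#' @param profiles Matrix or data frame of trip profiles (rows = trips).
#' @param k Number of clusters.
#' @param restarts,iter_max Restart and per-run iteration budget (their
#'   product is the total iteration budget of the search).
#' @param seed Integer seed.
#' @return A data frame with one row per trip: `cluster_id`, `tactic` (`SF` /
#'   `DF`; `NA` when `k != 2`) and `distance_to_centroid`, with the centroid
#'   matrix and total within-cluster sum of squares as attributes.
#' @export
kmeans_tactics <- function(profiles, k = 2, restarts = 100, iter_max = 100,
                           seed = 1) {
  x <- as.matrix(profiles)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (nrow(x) < k) stop("fewer profiles than clusters", call. = FALSE)
  km <- with_rng(seed, {
    for (attempt in 1:10) {
      fit <- tryCatch(
        stats::kmeans(x, k, nstart = restarts, iter.max = iter_max,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) {
      # Lloyd can abandon a restart on an empty cluster; Hartigan-Wong backup
      fit <- stats::kmeans(x, k, nstart = restarts, iter.max = iter_max)
    }
    fit
  })
  tactic <- rep(NA_character_, nrow(x))
  if (k == 2) {
    sf_cluster <- which.max(km$centers[, "perch"])
    tactic <- ifelse(km$cluster == sf_cluster, "SF", "DF")
  }
  dist_c <- sqrt(rowSums((x - km$centers[km$cluster, , drop = FALSE])^2))
  structure(data.frame(cluster_id = km$cluster, tactic = tactic,
                       distance_to_centroid = dist_c),
            centers = km$centers, tot_withinss = km$tot.withinss)
}
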