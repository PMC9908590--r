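#' Density-based clustering of abnormal patches
#'
#' Classical DBSCAN on patch grid coordinates `(i, j)` with Euclidean
#' metric: points with at least `min_samples` neighbors within `eps`
#' (including themselves) are core points, clusters are the
#' density-reachable sets, and non-core points reachable from no core are
#' noise. The default `eps = 1.5` makes the 8-neighborhood of a patch
#' adjacent, so "adjacent abnormal patches" aggregate into one lesion
#' cluster, and `min_samples = 4` suppresses isolated false positives.
#'
#' Determinism: cores are expanded in lexicographic `(i, j)` scan order, a
#' border point reachable from two clusters joins the first cluster that
#' claims it in that order, and cluster ids are renumbered by each
#' cluster's lexicographically smallest member, so the result is invariant
#' under input permutation.
#'
#' @param points Tibble with integer columns `i`, `j` and a
#'   `predicted_class` column; every row must be abnormal (the caller
#'   filters out normal predictions — enforced).
#' @param eps Neighborhood radius in grid units.
#' @param min_samples Core-point threshold (neighbors within `eps`,
#'   including the point itself).
#' @param normal_class Class id regarded as normal.
#' @return Input tibble plus a `cluster` column (integer id, `NA` = noise),
#'   rows in lexicographic `(i, j)` order.
#' @export
dbscan_clusters <- function(points, eps = 1.5, min_samples = 4,
                            normal_class = "c_normal") {
  stopifnot(eps > 0, min_samples >= 1)
  points <- as_tibble(points)
  if (!all(c("i", "j") %in% names(points))) {
    wsianno_abort("FORMAT_ERROR", "points need integer grid columns i and j")
  }
  if ("predicted_class" %in% names(points) &&
      any(points$predicted_class == normal_class)) {
    wsianno_abort("INPUT_CONTRACT",
      "normal-class points supplied; DBSCAN input must be abnormal patches only")
  }
  points <- points %>% arrange(.data$i, .data$j)
  n <- nrow(points)
  if (n == 0) return(points %>% mutate(cluster = integer()))
  xy <- cbind(points$i, points$j)
  d2 <- as.matrix(stats::dist(xy))^2
  nb <- lapply(seq_len(n), function(k) which(d2[k, ] <= eps^2))
  core <- lengths(nb) >= min_samples
  cluster <- rep(NA_integer_, n)
  cid <- 0L
  for (k in seq_len(n)) {
    if (!core[k] || !is.na(cluster[k])) next
    cid <- cid + 1L
    cluster[k] <- cid
    frontier <- k
    while (length(frontier) > 0) {
      cur <- frontier[1]; frontier <- frontier[-1]
      for (m in nb[[cur]]) {
        if (is.na(cluster[m])) {
          cluster[m] <- cid
          if (core[m]) frontier <- c(frontier, m)
        }
      }
    }
  }
  # canonical ids: order clusters by their lexicographically smallest member
  if (cid > 0) {
    first_member <- vapply(seq_len(cid), function(c) min(which(cluster == c)), integer(1))
    remap <- integer(cid)
    remap[order(first_member)] <- seq_len(cid)
    cluster <- ifelse(is.na(cluster), NA_integer_, remap[cluster])
  }
  points %>% mutate(cluster = cluster)
}

#' Fixed-size unordered caption bags per cluster
#'
#' A caption bag is the unit fed to a caption generator: an unordered,
#' size-capped multiset of a cluster's patches. Clusters larger than
#' `bag_size` are sampled uniformly without replacement; smaller clusters
#' are kept whole, or padded by resampling with replacement to exactly
#' `bag_size` when `pad = TRUE` (training mode).
#'
#' @param clustered Output of [dbscan_clusters()] (noise rows ignored).
#' @param bag_size Maximum patches per bag (e.g. 64 for training, 256 for
#'   prediction).
#' @param seed Sampling seed.
#' @param pad Resample small clusters up to `bag_size`.
#' @return Tibble (`cluster`, `bag_size`, `seed`, `patches` list-column of
#'   member tibbles with `i`, `j`).
#' @export
build_caption_bags <- function(clustered, bag_size = 64, seed = 1, pad = FALSE) {
  if (bag_size < 1) {
    wsianno_abort("FORMAT_ERROR", "bag_size must be at least 1")
  }
  members <- clustered %>% filter(!is.na(.data$cluster))
  ids <- sort(unique(members$cluster))
  bags <- lapply(ids, function(cid) {
    mem <- members %>% filter(.data$cluster == cid) %>% arrange(.data$i, .data$j)
    idx <- with_seed(substream_seed(seed, paste0("bag_", cid)), {
      if (nrow(mem) > bag_size) {
        sort(sample(seq_len(nrow(mem)), bag_size))
      } else if (pad && nrow(mem) < bag_size) {
        c(seq_len(nrow(mem)),
          sample(seq_len(nrow(mem)), bag_size - nrow(mem), replace = TRUE))
      } else {
        seq_len(nrow(mem))
      }
    })
    tibble(cluster = cid, bag_size = bag_size, seed = as.integer(seed),
           patches = list(mem[idx, c("i", "j")]))
  })
  bind_rows(bags)
}

#' Summary statistics of a clustering
#'
#' @param clustered Output of [dbscan_clusters()].
#' @return List with `n_clusters`, `n_noise`, `n_points`, and `clusters`, a
#'   tibble (`cluster`, `size`, `i0`, `i1`, `j0`, `j1` bounding boxes).
#' @export
cluster_summary <- function(clustered) {
  members <- clustered %>% filter(!is.na(.data$cluster))
  per <- if (nrow(members) == 0) {
    tibble(cluster = integer(), size = integer(),
           i0 = integer(), i1 = integer(), j0 = integer(), j1 = integer())
  } else {
    members %>%
      group_by(.data$cluster) %>%
      summarise(
        size = dplyr::n(),
        i0 = min(.data$i), i1 = max(.data$i),
        j0 = min(.data$j), j1 = max(.data$j),
        .groups = "drop"
      )
  }
  list(
    n_clusters = nrow(per),
    n_noise = sum(is.na(clustered$cluster)),
    n_points = nrow(clustered),
    clusters = per
  )
}
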