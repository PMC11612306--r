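#' Spatial cluster detection configuration
#'
#' @param neighborhood_radius_nm Linking distance (DBSCAN epsilon), nm.
#' @param min_localizations Minimum detections to call a cluster (also the
#'   DBSCAN core-point threshold).
#' @param size_threshold_nm Boundary between small and large clusters, nm;
#'   the conventional value is 200.
#' @return An object of class `spatial_config`.
#' @export
spatial_config <- function(neighborhood_radius_nm = 50,
                           min_localizations = 10,
                           size_threshold_nm = 200) {
  vals <- c(neighborhood_radius_nm, min_localizations, size_threshold_nm)
  if (!is.numeric(vals) || any(vals <= 0)) {
    abort("All spatial_config parameters must be positive.")
  }
  structure(
    list(
      neighborhood_radius_nm = neighborhood_radius_nm,
      min_localizations = as.integer(min_localizations),
      size_threshold_nm = size_threshold_nm
    ),
    class = "spatial_config"
  )
}

# Maximum pairwise distance; goes through the convex hull so large clusters
# stay cheap.
max_pairwise_distance <- function(x, y) {
  n <- length(x)
  if (n <= 1L) return(0)
  if (n > 3L) {
    hull <- grDevices::chull(x, y)
    x <- x[hull]
    y <- y[hull]
  }
  max(stats::dist(cbind(x, y)), 0)
}

#' Detect spatial clusters in a localization table
#'
#' Groups detections into density-connected components (DBSCAN with epsilon
#' `neighborhood_radius_nm` and core threshold `min_localizations`) and
#' summarizes each component: centroid, diameter (maximum pairwise member
#' distance), and a small/large class against `size_threshold_nm`.
#' Detections not absorbed by any cluster are noise and are left out.
#'
#' @param table A localization table (tibble with `x_nm`, `y_nm`; see
#'   [simulate_live_cell()] or [read_localizations()]).
#' @param cfg A [spatial_config()].
#' @return A tibble with one row per cluster, sorted by descending member
#'   count (ties by centroid x): `cluster_id`, `n`, `centroid_x_nm`,
#'   `centroid_y_nm`, `diameter_nm`, `size_class`, and `member_rows` (a
#'   list-column of row indices into `table`).
#' @seealso [annotate_localizations()], [summarize_cluster_counts()]
#' @export
detect_spatial_clusters <- function(table, cfg = spatial_config()) {
  stopifnot(inherits(cfg, "spatial_config"))
  empty <- tibble::tibble(
    cluster_id = integer(0), n = integer(0),
    centroid_x_nm = numeric(0), centroid_y_nm = numeric(0),
    diameter_nm = numeric(0),
    size_class = character(0),
    member_rows = list()
  )
  if (nrow(table) == 0L) return(empty)

  labels <- dbscan_labels(table$x_nm, table$y_nm,
                          eps = cfg$neighborhood_radius_nm,
                          min_pts = cfg$min_localizations)
  if (all(labels == 0L)) return(empty)

  members <- split(seq_len(nrow(table)), labels)
  members <- members[names(members) != "0"]
  out <- purrr::map_dfr(members, function(rows) {
    xs <- table$x_nm[rows]
    ys <- table$y_nm[rows]
    diam <- max_pairwise_distance(xs, ys)
    tibble::tibble(
      n = length(rows),
      centroid_x_nm = mean(xs),
      centroid_y_nm = mean(ys),
      diameter_nm = diam,
      size_class = classify_cluster_size(diam, cfg$size_threshold_nm),
      member_rows = list(rows)
    )
  })
  out <- out[out$n >= cfg$min_localizations, , drop = FALSE]
  out <- dplyr::arrange(out, dplyr::desc(.data$n), .data$centroid_x_nm)
  dplyr::mutate(out, cluster_id = dplyr::row_number(), .before = 1L)
}

#' Classify cluster size against the small/large boundary
#'
#' A cluster is `small` when its diameter is strictly below the threshold
#' and `large` otherwise (a diameter exactly at the boundary is `large`).
#'
#' @param diameter_nm Cluster diameter(s), nm (>= 0); vectorized.
#' @param threshold_nm Small/large boundary, nm (default 200).
#' @return Character vector of `"small"` / `"large"`.
#' @examples
#' classify_cluster_size(c(150, 350), 200)
#' @export
classify_cluster_size <- function(diameter_nm, threshold_nm = 200) {
  if (any(diameter_nm < 0)) abort("`diameter_nm` must be >= 0.")
  ifelse(diameter_nm < threshold_nm, "small", "large")
}

#' Count clusters per size class
#'
#' @param clusters A cluster tibble from [detect_spatial_clusters()] (any
#'   data frame with a `size_class` column).
#' @return A one-row tibble with `n_small`, `n_large`, `n_total`.
#' @export
summarize_cluster_counts <- function(clusters) {
  sc <- if (nrow(clusters)) clusters$size_class else character(0)
  tibble::tibble(
    n_small = sum(sc == "small"),
    n_large = sum(sc == "large"),
    n_total = length(sc)
  )
}

#' Annotate a localization table with detected cluster ids
#'
#' @param table The localization table that was clustered.
#' @param clusters The result of [detect_spatial_clusters()] on `table`.
#' @return `table` with an added `cluster_id` column (`NA` for noise).
#' @export
annotate_localizations <- function(table, clusters) {
  ids <- rep(NA_integer_, nrow(table))
  for (i in seq_len(nrow(clusters))) {
    ids[clusters$member_rows[[i]]] <- clusters$cluster_id[i]
  }
  dplyr::mutate(table, cluster_id = ids)
}
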