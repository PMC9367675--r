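# Synthetic tissue generator: two-population marked point patterns with
# known ground truth, at densities and window sizes comparable to a
# scanned tissue region of interest.  Two interaction models:
#
#   csr           - both phenotypes are independent homogeneous Poisson
#                   processes (no interaction; the null baseline).
#   shared_parent - a Neyman-Scott cluster process in which both
#                   phenotypes scatter (Gaussian sd = sigma) around one
#                   common set of latent parent points.  Sharing parents
#                   induces cross-type co-location whose strength grows
#                   as sigma shrinks; sigma at the window scale recovers
#                   CSR-like behaviour.
#
# Ground truth is carried in a `true_label` column that the analysis path
# never reads (it is excluded from the marker set by construction).

#' Synthetic tissue configuration
#'
#' @param window rectangle `c(xmin, ymin, xmax, ymax)` in microns;
#'   default a 1000 x 1000 um region, comparable to a scanned 200x field.
#' @param lambda_a,lambda_b intensities of the two phenotypes in cells
#'   per square micron.  The default `1e-4` (about 100 cells per default
#'   window) reflects a rare infiltrating phenotype; real sections range
#'   over roughly `1e-5`–`1e-4` for such populations.
#' @param model `"csr"` or `"shared_parent"`.
#' @param parent_intensity latent parent intensity per square micron
#'   (shared_parent only).
#' @param sigma Gaussian dispersion of offspring around their parent in
#'   microns (shared_parent only); smaller sigma = stronger co-location.
#' @param marker_noise list with `mean_pos`, `mean_neg`, `sd`: marker
#'   intensities are drawn Normal(mean, sd), truncated at zero, with the
#'   mean chosen by whether the marker is positive for the cell's
#'   ground-truth phenotype.
#' @param topology `"plane"` (default) or `"torus"` (periodic window, for
#'   exact closed-form calibration).
#' @param type_a,type_b ground-truth labels (default `"ILC2"`, `"Treg"`).
#' @param seed optional integer seed; a seeded configuration regenerates
#'   the identical table on every call.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(window = c(0, 0, 1000, 1000),
                             lambda_a = 1e-4, lambda_b = 1e-4,
                             model = c("csr", "shared_parent"),
                             parent_intensity = 5e-5, sigma = 10,
                             marker_noise = list(mean_pos = 10,
                                                 mean_neg = 1, sd = 0.5),
                             topology = c("plane", "torus"),
                             type_a = "ILC2", type_b = "Treg",
                             seed = NULL) {
  model <- match.arg(model)
  topology <- match.arg(topology)
  if (length(window) != 4 || window[3] <= window[1] || window[4] <= window[2])
    stop("window must be c(xmin, ymin, xmax, ymax) with positive area",
         call. = FALSE)
  if (lambda_a < 0 || lambda_b < 0)
    stop("intensities must be >= 0", call. = FALSE)
  if (model == "shared_parent") {
    if (!(sigma > 0)) stop("sigma must be > 0 for shared_parent",
                           call. = FALSE)
    if (parent_intensity <= 0 && (lambda_a > 0 || lambda_b > 0))
      stop("parent_intensity must be > 0 when offspring intensities are ",
           "positive", call. = FALSE)
  }
  if (!(marker_noise$mean_pos > marker_noise$mean_neg))
    stop("marker_noise$mean_pos must exceed mean_neg", call. = FALSE)
  if (marker_noise$sd < 0) stop("marker_noise$sd must be >= 0", call. = FALSE)
  structure(list(window = unname(window), lambda_a = lambda_a,
                 lambda_b = lambda_b, model = model,
                 parent_intensity = parent_intensity, sigma = sigma,
                 marker_noise = marker_noise, topology = topology,
                 type_a = type_a, type_b = type_b, seed = seed),
            class = "synthetic_config")
}

win_area <- function(w) (w[3] - w[1]) * (w[4] - w[2])

finish_tissue <- function(xa, ya, xb, yb, config, sample_id, roi_id,
                          with_markers) {
  w <- config$window
  n <- length(xa) + length(xb)
  df <- tibble::tibble(
    cell_id = sprintf("c%06d", seq_len(n)),
    sample_id = sample_id, roi_id = roi_id,
    x = c(xa, xb), y = c(ya, yb),
    true_label = c(rep(config$type_a, length(xa)),
                   rep(config$type_b, length(xb))))
  df <- attach_marker_columns(df, config, with_markers)
  cell_table(df, markers = c("CD4", "CD8", "CD127", "GATA3", "Foxp3"),
             marker_type = "continuous", window = w)
}

#' Simulate complete spatial randomness
#'
#' Both phenotype counts are Poisson with mean intensity times window
#' area; positions are i.i.d. uniform in the window.  Marker intensities
#' consistent with each cell's ground-truth label are attached (see
#' [attach_marker_intensities()]).
#'
#' @param config a [synthetic_config()] with `model = "csr"`.
#' @param sample_id,roi_id identifiers written into the table.
#' @return a continuous `cell_table` with a `true_label` column.
#' @export
simulate_csr <- function(config, sample_id = "S1", roi_id = "R1") {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$model != "csr") stop("config$model is not 'csr'", call. = FALSE)
  w <- config$window
  if (win_area(w) <= 0) stop("window has zero area", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  na <- rpois(1, config$lambda_a * win_area(w))
  nb <- rpois(1, config$lambda_b * win_area(w))
  finish_tissue(runif(na, w[1], w[3]), runif(na, w[2], w[4]),
                runif(nb, w[1], w[3]), runif(nb, w[2], w[4]),
                config, sample_id, roi_id, with_markers = TRUE)
}

#' Simulate the shared-parent cluster process
#'
#' Latent parents form a Poisson process; each phenotype's cells are
#' Poisson in number, each assigned to a uniformly chosen parent and
#' displaced by isotropic Gaussian noise with sd `sigma`.  Both
#' phenotypes share the same parents, which induces cross-type
#' attraction.  Marginal intensities match `lambda_a` / `lambda_b` in
#' expectation.  On the plane, parents are laid in a window buffered by
#' 4 sigma and offspring falling outside the target window are dropped
#' (plus-sampling, so the interior intensity is unbiased); on the torus,
#' coordinates wrap.
#'
#' @param config a [synthetic_config()] with `model = "shared_parent"`.
#' @inheritParams simulate_csr
#' @return a continuous `cell_table` with a `true_label` column.
#' @export
simulate_shared_parent <- function(config, sample_id = "S1", roi_id = "R1") {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$model != "shared_parent")
    stop("config$model is not 'shared_parent'", call. = FALSE)
  w <- config$window
  if (win_area(w) <= 0) stop("window has zero area", call. = FALSE)
  if (config$parent_intensity <= 0 &&
      (config$lambda_a > 0 || config$lambda_b > 0))
    stop("parent_intensity must be > 0 when offspring intensities are ",
         "positive", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  torus <- config$topology == "torus"
  buf <- if (torus) 0 else 4 * config$sigma
  bw <- c(w[1] - buf, w[2] - buf, w[3] + buf, w[4] + buf)
  n_par <- rpois(1, config$parent_intensity * win_area(bw))
  px <- runif(n_par, bw[1], bw[3]); py <- runif(n_par, bw[2], bw[4])
  offspring <- function(lambda) {
    if (n_par == 0 || lambda <= 0) return(list(x = numeric(0), y = numeric(0)))
    n <- rpois(1, lambda * win_area(bw))
    pid <- sample.int(n_par, n, replace = TRUE)
    x <- px[pid] + rnorm(n, 0, config$sigma)
    y <- py[pid] + rnorm(n, 0, config$sigma)
    if (torus) {
      x <- w[1] + (x - w[1]) %% (w[3] - w[1])
      y <- w[2] + (y - w[2]) %% (w[4] - w[2])
    } else {
      keep <- x >= w[1] & x <= w[3] & y >= w[2] & y <= w[4]
      x <- x[keep]; y <- y[keep]
    }
    list(x = x, y = y)
  }
  A <- offspring(config$lambda_a)
  B <- offspring(config$lambda_b)
  finish_tissue(A$x, A$y, B$x, B$y, config, sample_id, roi_id,
                with_markers = TRUE)
}

#' Simulate one tissue region
#'
#' Dispatches on `config$model`.
#'
#' @inheritParams simulate_csr
#' @return a continuous `cell_table` with a `true_label` column.
#' @export
simulate_tissue <- function(config, sample_id = "S1", roi_id = "R1") {
  switch(config$model,
         csr = simulate_csr(config, sample_id, roi_id),
         shared_parent = simulate_shared_parent(config, sample_id, roi_id))
}

attach_marker_columns <- function(df, config, with_markers = TRUE) {
  mk <- c("CD4", "CD8", "CD127", "GATA3", "Foxp3")
  pos_for <- list()
  pos_for[[config$type_a]] <- c("CD127", "GATA3")  # ILC2-like pattern
  pos_for[[config$type_b]] <- c("CD4", "Foxp3")    # Treg-like pattern
  mn <- config$marker_noise
  n <- nrow(df)
  for (m in mk) {
    mu <- rep(mn$mean_neg, n)
    for (lab in names(pos_for))
      mu[df$true_label == lab & m %in% pos_for[[lab]]] <- mn$mean_pos
    df[[m]] <- if (with_markers) pmax(0, rnorm(n, mu, mn$sd)) else mu
  }
  df
}

#' Redraw marker intensities consistent with ground-truth labels
#'
#' For each cell, every marker positive for the cell's ground-truth
#' phenotype (CD127/GATA3 for the ILC2-like type, CD4/Foxp3 for the
#' Treg-like type) is drawn Normal(`mean_pos`, `sd`) and every other
#' marker Normal(`mean_neg`, `sd`), truncated at zero.  Cells with any
#' other label get all-negative markers.
#'
#' @param table a `cell_table` with a `true_label` column.
#' @param config a [synthetic_config()] (uses `marker_noise`, `type_a`,
#'   `type_b`).
#' @return the table with continuous marker columns replaced.
#' @export
attach_marker_intensities <- function(table, config) {
  stopifnot("true_label" %in% names(table))
  df <- attach_marker_columns(tibble::as_tibble(table), config, TRUE)
  cell_table(df, markers = c("CD4", "CD8", "CD127", "GATA3", "Foxp3"),
             marker_type = "continuous", window = attr(table, "window"))
}

#' Default cohort configurations
#'
#' Three study groups ordered by cross-type attraction strength: a
#' "rejection"-like group (shared parents, sigma = 5 um), a
#' "nonrejection"-like group (sigma = 15 um) and a "control" group with
#' no interaction (CSR), all at equal phenotype intensities.
#'
#' @param lambda per-type intensity (cells per square micron).
#' @param window region rectangle in microns.
#' @param parent_intensity latent parent intensity.
#' @param sigma_rejection,sigma_nonrejection cluster dispersions.
#' @return named list of three [synthetic_config()]s.
#' @export
cohort_configs <- function(lambda = 1e-4, window = c(0, 0, 1000, 1000),
                           parent_intensity = 5e-5,
                           sigma_rejection = 5, sigma_nonrejection = 15) {
  list(
    rejection = synthetic_config(window, lambda, lambda,
                                 model = "shared_parent",
                                 parent_intensity = parent_intensity,
                                 sigma = sigma_rejection),
    nonrejection = synthetic_config(window, lambda, lambda,
                                    model = "shared_parent",
                                    parent_intensity = parent_intensity,
                                    sigma = sigma_nonrejection),
    control = synthetic_config(window, lambda, lambda, model = "csr"))
}

#' Simulate a cohort of samples across study groups
#'
#' Generates per-sample tables for three groups whose configurations are
#' ordered by attraction strength (see [cohort_configs()]), each sample
#' comprising `n_roi` independently simulated regions of interest
#' (matching the handful of regions a pathologist scans per section).
#'
#' @param n_rejection,n_nonrejection,n_control samples per group (the
#'   cohort must not be empty).
#' @param configs named list of per-group [synthetic_config()]s with
#'   elements `rejection`, `nonrejection`, `control`.
#' @param n_roi regions of interest per sample.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return one combined continuous `cell_table` with `sample_id` of the
#'   form `<group>_<i>`, a `group` column, and `true_label` ground truth.
#' @export
make_cohort <- function(n_rejection = 3, n_nonrejection = 3, n_control = 3,
                        configs = cohort_configs(), n_roi = 5,
                        seed = NULL) {
  ns <- c(rejection = n_rejection, nonrejection = n_nonrejection,
          control = n_control)
  if (sum(ns) == 0) stop("empty cohort", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tabs <- list()
  for (g in names(ns)) {
    if (ns[[g]] == 0) next
    cfg <- configs[[g]]
    if (is.null(cfg)) stop("no config for group '", g, "'", call. = FALSE)
    cfg$seed <- NULL  # one stream for the whole cohort
    for (i in seq_len(ns[[g]])) {
      sid <- sprintf("%s_%d", g, i)
      for (r in seq_len(n_roi)) {
        tab <- simulate_tissue(cfg, sample_id = sid,
                               roi_id = sprintf("R%d", r))
        tab$group <- g
        tabs[[length(tabs) + 1L]] <- tibble::as_tibble(tab)
      }
    }
  }
  df <- dplyr::bind_rows(tabs)
  cell_table(df, markers = c("CD4", "CD8", "CD127", "GATA3", "Foxp3"),
             marker_type = "continuous",
             window = configs[[1]]$window)
}
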