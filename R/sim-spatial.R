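#' Configuration for the spatial-lattice simulator
#'
#' @param lattice `"hex"` (offset rows, center-to-center distance = `pitch`,
#'   as on a Visium slide) or `"square"`.
#' @param n_rows,n_cols Lattice dimensions.
#' @param pitch Center-to-center spacing, in the coordinate units used by
#'   all downstream distance cutoffs.
#' @param n_genes Number of genes (receptor-ligand pairs draw from these).
#' @param n_rl_pairs Number of receptor-ligand pairs to name (pair `i` is
#'   gene `2i-1` as ligand, gene `2i` as receptor).
#' @param planted_pairs List of planted microdomains; each element is a list
#'   with `pair` (index into the named pairs), `center` (x, y), `radius`
#'   (same units as `pitch`) and `fold` (>= 1) applied to both the ligand
#'   and the receptor mean inside the disc.
#' @param base_mu Baseline negative-binomial mean per gene (default 10,
#'   a well-detected signaling gene at spot resolution).
#' @param nb_dispersion Negative-binomial size (default 25: mild
#'   overdispersion about a homogeneous baseline).
#' @param n_regions Number of vertical-band region clusters to label.
#' @param condition Condition label attached to the slide.
#' @param seed Integer seed.
#' @return An object of class `spatial_sim_config`.
#' @export
spatial_sim_config <- function(lattice = c("hex", "square"),
                               n_rows = 20L, n_cols = 25L, pitch = 1,
                               n_genes = 40L, n_rl_pairs = 10L,
                               planted_pairs = list(),
                               base_mu = 10, nb_dispersion = 25,
                               n_regions = 2L, condition = "cond1",
                               seed = 1L) {
  lattice <- match.arg(lattice)
  stop_if_not(n_rows >= 1 && n_cols >= 1, "lattice must have >= 1 location")
  stop_if_not(pitch > 0, "pitch must be positive")
  stop_if_not(2L * n_rl_pairs <= n_genes,
              "need at least 2 genes per receptor-ligand pair")
  for (pp in planted_pairs) {
    stop_if_not(is.list(pp) && all(c("pair", "center", "radius", "fold")
                                   %in% names(pp)),
                "planted pair needs fields pair, center, radius, fold")
    stop_if_not(pp$fold >= 1, "planted fold-change must be >= 1")
  }
  cfg <- list(lattice = lattice, n_rows = as.integer(n_rows),
              n_cols = as.integer(n_cols), pitch = pitch,
              n_genes = as.integer(n_genes), n_rl_pairs = as.integer(n_rl_pairs),
              planted_pairs = planted_pairs, base_mu = base_mu,
              nb_dispersion = nb_dispersion, n_regions = as.integer(n_regions),
              condition = condition, seed = as.integer(seed))
  class(cfg) <- "spatial_sim_config"
  cfg
}

lattice_coords <- function(lattice, n_rows, n_cols, pitch) {
  row <- rep(seq_len(n_rows), each = n_cols)
  col <- rep(seq_len(n_cols), times = n_rows)
  if (lattice == "hex") {
    x <- (col - 1) * pitch + ((row - 1) %% 2) * pitch / 2
    y <- (row - 1) * pitch * sqrt(3) / 2
  } else {
    x <- (col - 1) * pitch
    y <- (row - 1) * pitch
  }
  data.frame(row = row, col = col, x = x, y = y)
}

#' Simulate a spatial expression map with planted ligand-receptor microdomains
#'
#' Locations sit on a hex or square lattice; expression is i.i.d. negative
#' binomial per gene, and inside each planted microdomain the ligand and
#' receptor means of the planted pair are multiplied by its fold-change.
#' Region labels are vertical bands; `planted_positive` in the truth marks
#' the in-disc locations of planted pairs.
#'
#' @param config A [spatial_sim_config()] object.
#' @return List with `map` (class `spatial_map`) and `truth` (list with
#'   `planted_positive`, a locations x pairs logical matrix).
#' @export
simulate_spatial <- function(config) {
  stopifnot(inherits(config, "spatial_sim_config"))
  set.seed(config$seed)
  co <- lattice_coords(config$lattice, config$n_rows, config$n_cols,
                       config$pitch)
  n_loc <- nrow(co)
  ## microdomains must lie within lattice bounds
  for (pp in config$planted_pairs) {
    stop_if_not(pp$center[1] >= min(co$x) - 1e-9 &&
                pp$center[1] <= max(co$x) + 1e-9 &&
                pp$center[2] >= min(co$y) - 1e-9 &&
                pp$center[2] <= max(co$y) + 1e-9,
                "microdomain center outside lattice bounds")
  }
  genes <- paste0("g", seq_len(config$n_genes))
  pairs <- data.frame(
    ligand = genes[2 * seq_len(config$n_rl_pairs) - 1],
    receptor = genes[2 * seq_len(config$n_rl_pairs)],
    stringsAsFactors = FALSE)

  gene_mu <- config$base_mu * exp(rnorm(config$n_genes, 0, 0.2))
  mu <- matrix(gene_mu, config$n_genes, n_loc,
               dimnames = list(genes, NULL))

  planted_positive <- matrix(FALSE, n_loc, config$n_rl_pairs,
                             dimnames = list(NULL, paste0("pair", seq_len(config$n_rl_pairs))))
  ## reject incompatible overlaps: the same gene boosted by two different
  ## folds in overlapping discs
  boost <- matrix(1, config$n_genes, n_loc, dimnames = dimnames(mu))
  for (pp in config$planted_pairs) {
    inside <- (co$x - pp$center[1])^2 + (co$y - pp$center[2])^2 <=
      pp$radius^2 + 1e-12
    gl <- pairs$ligand[pp$pair]; gr <- pairs$receptor[pp$pair]
    for (g in c(gl, gr)) {
      prev <- boost[g, inside]
      if (any(prev != 1 & prev != pp$fold)) {
        stop("overlapping planted regions assign incompatible fold-changes to gene ",
             g, call. = FALSE)
      }
      boost[g, inside] <- pp$fold
    }
    planted_positive[inside, pp$pair] <- TRUE
  }
  mu <- mu * boost
  expr <- matrix(rnbinom(length(mu), size = config$nb_dispersion, mu = mu),
                 nrow(mu), ncol(mu), dimnames = dimnames(mu))

  region <- paste0("region", cut(co$x, breaks = config$n_regions,
                                 labels = FALSE, include.lowest = TRUE))
  coords <- data.frame(location = sprintf("loc%05d", seq_len(n_loc)),
                       x = co$x, y = co$y, row = co$row, col = co$col,
                       slide = "slide1", region = region,
                       condition = config$condition,
                       stringsAsFactors = FALSE)
  colnames(expr) <- coords$location
  rownames(planted_positive) <- coords$location

  map <- structure(list(coords = coords, expr = expr, pairs = pairs,
                        pitch = config$pitch, units = "lattice"),
                   class = "spatial_map")
  list(map = map, truth = list(planted_positive = planted_positive))
}

#' @export
print.spatial_map <- function(x, ...) {
  cat("Spatial map:", nrow(x$coords), "locations,",
      nrow(x$expr), "genes,", length(unique(x$coords$slide)), "slide(s),",
      "pitch", x$pitch, x$units, "units\n")
  invisible(x)
}

## deterministic, area-balanced niche center layout on the unit square:
## one central domain plus a ring (a quincunx for 5 niches)
niche_centers <- function(n_niches) {
  if (n_niches == 1L) return(cbind(0.5, 0.5))
  if (n_niches <= 4L) {
    ang <- 2 * pi * seq_len(n_niches) / n_niches + pi / 4
    return(cbind(0.5 + 0.3 * cos(ang), 0.5 + 0.3 * sin(ang)))
  }
  ang <- 2 * pi * seq_len(n_niches - 1L) / (n_niches - 1L) + pi / 4
  rbind(cbind(0.5 + 0.33 * cos(ang), 0.5 + 0.33 * sin(ang)),
        cbind(0.5, 0.5))
}

#' Simulate a segmented-cell map with planted spatial niches
#'
#' Cells are placed uniformly in a square field of view; niches are the
#' Voronoi regions of a fixed, area-balanced arrangement of niche centers
#' (contiguous geometric domains),
#' and each niche draws cell types from its own composition profile. The
#' default profiles give each niche one dominant and one secondary type,
#' the kind of separation seen between, e.g., follicle, crypt-top and
#' stromal neighborhoods.
#'
#' @param n_cells Number of cells.
#' @param n_niches Number of planted niches.
#' @param n_types Number of cell types.
#' @param fov_size Side length of the square field of view, in the same
#'   units as neighbor-search radii (think micrometers). The default
#'   scales with `sqrt(n_cells)` so cell density — and hence the number
#'   of neighbors inside a fixed-radius cap — is the same at every size
#'   (about 10 cells within 30 units at the 10,000-cell default).
#' @param type_profiles Optional `n_niches x n_types` row-stochastic matrix
#'   of composition profiles.
#' @param seed Integer seed.
#' @return List with `cells` (data.frame: `cell`, `x`, `y`, `fov`, `type`)
#'   and `truth` (data.frame with the planted `niche` per cell).
#' @export
simulate_niche_map <- function(n_cells = 10000L, n_niches = 5L, n_types = 8L,
                               fov_size = NULL, type_profiles = NULL,
                               seed = 1L) {
  stop_if_not(n_niches >= 1, "need at least one niche")
  stop_if_not(n_types >= 2, "need at least two cell types")
  if (is.null(fov_size)) fov_size <- 1650 * sqrt(n_cells / 10000)
  set.seed(seed)
  if (is.null(type_profiles)) {
    ## one dominant type per niche; secondary types are drawn from the
    ## types never used as dominants, so no niche's marker type is another
    ## niche's secondary signal
    n_dom <- min(n_niches, n_types - 1L)
    sec_pool <- setdiff(seq_len(n_types), seq_len(n_dom))
    if (!length(sec_pool)) sec_pool <- seq_len(n_types)
    type_profiles <- matrix(0.3 / (n_types - 2), n_niches, n_types)
    for (i in seq_len(n_niches)) {
      dom <- 1 + (i - 1) %% n_dom
      sec <- sec_pool[1 + (i - 1) %% length(sec_pool)]
      type_profiles[i, ] <- 0.3 / (n_types - 2)
      type_profiles[i, dom] <- 0.5
      type_profiles[i, sec] <- 0.2
    }
    type_profiles <- type_profiles / rowSums(type_profiles)
  }
  stop_if_not(all(abs(rowSums(type_profiles) - 1) < 1e-6),
              "type_profiles rows must sum to 1")
  x <- runif(n_cells, 0, fov_size)
  y <- runif(n_cells, 0, fov_size)
  centers <- niche_centers(n_niches) * fov_size
  d2 <- outer(x^2 + y^2, rowSums(centers^2), "+") -
    2 * cbind(x, y) %*% t(centers)
  niche <- max.col(-d2)
  type <- vapply(niche, function(k)
    sample.int(n_types, 1L, prob = type_profiles[k, ]), integer(1))
  cells <- data.frame(cell = sprintf("c%06d", seq_len(n_cells)),
                      x = x, y = y, fov = "fov1",
                      type = factor(paste0("type", type),
                                    levels = paste0("type", seq_len(n_types))),
                      stringsAsFactors = FALSE)
  list(cells = cells,
       truth = data.frame(cell = cells$cell, niche = niche,
                          stringsAsFactors = FALSE))
}
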