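## Seeded generators for every input the pipeline consumes: spot maps with
## deconvolved abundances and counts, mIHC-style point patterns, and paired
## pre/post patient cohorts. All generators are pure functions of
## (parameters, seed).

#' Specify a spatial niche for the map generator
#'
#' A niche is a Gaussian hotspot: member cell types receive an abundance
#' bump `strength * exp(-d^2 / (2 spread^2))` around `center` (added to the
#' Dirichlet background before per-spot renormalization), and the niche's
#' ligand-receptor genes are scaled by
#' `1 + (elevation - 1) * exp(-d^2 / (2 spread^2))` so their expression is
#' elevated inside the niche.
#'
#' @param center Numeric `c(x, y)` niche center (map coordinate units).
#' @param spread Gaussian kernel sd, > 0.
#' @param member_types Non-empty character vector of member cell types.
#' @param lr_pairs List of `c(ligand, receptor)` gene pairs elevated inside
#'   the niche (may be empty).
#' @param elevation Expression multiplier at the niche center, >= 1.
#' @param strength Peak abundance bump added for member types (default 3;
#'   the Dirichlet background of each spot sums to 1, so 3 makes members
#'   clearly dominant at the center).
#' @param allocation How the bump is shared among `member_types`:
#'   `"shared"` (default) gives every member type the full kernel bump at
#'   every spot, so members co-occur within spots; `"mosaic"` assigns each
#'   spot's bump to one member type drawn uniformly, emulating a niche
#'   whose constituent cell types interleave spot by spot (each spot
#'   dominated by one type) while sharing the same region.
#' @return Object of class `"niche_spec"`.
#' @export
niche_spec <- function(center, spread, member_types, lr_pairs = list(),
                       elevation = 1, strength = 3,
                       allocation = c("shared", "mosaic")) {
  allocation <- match.arg(allocation)
  stopifnot(
    "center must be c(x, y)" = is.numeric(center) && length(center) == 2L,
    "spread must be > 0" = is.numeric(spread) && length(spread) == 1L &&
      spread > 0,
    "member_types must be non-empty" = is.character(member_types) &&
      length(member_types) >= 1L,
    "elevation must be >= 1" = is.numeric(elevation) && elevation >= 1,
    "strength must be >= 0" = is.numeric(strength) && strength >= 0
  )
  if (length(lr_pairs) && !all(vapply(lr_pairs, length, 1L) == 2L)) {
    stop("each lr_pair must be c(ligand, receptor)")
  }
  structure(list(center = as.numeric(center), spread = spread,
                 member_types = member_types, lr_pairs = lr_pairs,
                 elevation = elevation, strength = strength,
                 allocation = allocation),
            class = "niche_spec")
}

default_cell_types <- function() {
  c("malignant", "endothelial", "fibroblast", "T_NK",
    "B", "macrophage", "DC", "mast")
}

#' Simulate a deconvolved spatial map with optional niches
#'
#' Generates (i) spots on a jittered hexagonal-like grid, (ii) a per-spot
#' cell-type abundance matrix: symmetric Dirichlet background plus, for
#' each niche's member types, a Gaussian kernel bump, renormalized per
#' spot to sum 1, and (iii) a sparse gene count matrix: per-spot library
#' size ~ lognormal, gene means a mixture of per-type marker signatures
#' weighted by the spot's abundances, ligand-receptor genes scaled by the
#' niche elevation kernel, counts ~ Poisson. With no niches the abundances
#' are exactly the Dirichlet background (no spatial structure).
#'
#' The grid spans roughly the unit square; niche centers and spreads are
#' in those units.
#'
#' @param n_spots Number of spots (>= 4).
#' @param cell_types Character vector of >= 2 cell-type names.
#' @param niches List of [niche_spec()] objects (may be empty).
#' @param baseline_conc Symmetric Dirichlet concentration of the
#'   background (default 1).
#' @param seed Integer seed; identical seeds give identical outputs.
#' @param markers_per_type Marker genes simulated per cell type (default 5).
#' @param lib_size_meanlog,lib_size_sdlog Lognormal library-size
#'   parameters (default `log(5000)`, 0.3).
#' @param jitter_sd Positional jitter sd as a fraction of spot spacing
#'   (default 0.08).
#' @return List of class `"spatial_map_sim"`: `spots` (spot table),
#'   `abundance` (spots x types matrix, rows sum to 1), `counts`
#'   (genes x spots `dgCMatrix`), `gene_ids`, `lr_genes`, `params`.
#' @examples
#' sim <- simulate_spatial_map(100, c("A", "B"), seed = 1)
#' rowSums(sim$abundance)[1:3]
#' @export
simulate_spatial_map <- function(n_spots,
                                 cell_types = default_cell_types(),
                                 niches = list(),
                                 baseline_conc = 1,
                                 seed = 1L,
                                 markers_per_type = 5L,
                                 lib_size_meanlog = log(5000),
                                 lib_size_sdlog = 0.3,
                                 jitter_sd = 0.08) {
  stopifnot("n_spots must be >= 4" = n_spots >= 4L,
            "need >= 2 cell types" = length(cell_types) >= 2L,
            "baseline_conc must be > 0" = baseline_conc > 0)
  if (inherits(niches, "niche_spec")) niches <- list(niches)
  for (nc in niches) {
    stopifnot(inherits(nc, "niche_spec"))
    unknown <- setdiff(nc$member_types, cell_types)
    if (length(unknown)) {
      stop("niche member type(s) not in cell_types: ",
           paste(unknown, collapse = ", "))
    }
  }
  K <- length(cell_types)
  with_seed(seed, {
    ## jittered hex-like grid on ~ the unit square
    n_rows <- ceiling(sqrt(n_spots))
    n_cols <- ceiling(n_spots / n_rows)
    row_i <- rep(seq_len(n_rows), each = n_cols)[seq_len(n_spots)]
    col_i <- rep(seq_len(n_cols), times = n_rows)[seq_len(n_spots)]
    dx <- 1 / n_cols
    dy <- 1 / n_rows
    x <- (col_i - 0.5) * dx + ifelse(row_i %% 2 == 0, dx / 2, 0) +
      rnorm(n_spots, 0, jitter_sd * dx)
    y <- (row_i - 0.5) * dy + rnorm(n_spots, 0, jitter_sd * dy)
    spots <- data.frame(
      spot_id = sprintf("spot_%04d", seq_len(n_spots)),
      in_tissue = TRUE, array_row = row_i, array_col = col_i,
      x = x, y = y, stringsAsFactors = FALSE
    )
    bbox <- spot_bbox(x, y)
    ## Dirichlet background
    G <- matrix(rgamma(n_spots * K, shape = baseline_conc), n_spots, K)
    A <- G / rowSums(G)
    colnames(A) <- cell_types
    rownames(A) <- spots$spot_id
    ## niche bumps on member types
    kernels <- lapply(niches, function(nc) {
      if (nc$center[1] < bbox[1] || nc$center[1] > bbox[2] ||
          nc$center[2] < bbox[3] || nc$center[2] > bbox[4]) {
        warning("niche center (", nc$center[1], ", ", nc$center[2],
                ") lies outside the spot bounding box")
      }
      d2 <- (x - nc$center[1])^2 + (y - nc$center[2])^2
      exp(-d2 / (2 * nc$spread^2))
    })
    if (length(niches)) {
      for (ii in seq_along(niches)) {
        nc <- niches[[ii]]
        if (identical(nc$allocation, "mosaic") &&
            length(nc$member_types) > 1L) {
          owner <- sample(nc$member_types, n_spots, replace = TRUE)
          for (tp in nc$member_types) {
            hit <- owner == tp
            A[hit, tp] <- A[hit, tp] + nc$strength * kernels[[ii]][hit]
          }
        } else {
          for (tp in nc$member_types) {
            A[, tp] <- A[, tp] + nc$strength * kernels[[ii]]
          }
        }
      }
      A <- A / rowSums(A)
    }
    ## genes: per-type marker blocks + ligand-receptor genes
    marker_ids <- unlist(lapply(cell_types, function(tp) {
      sprintf("%s_mk%d", tp, seq_len(markers_per_type))
    }))
    lr_genes <- unique(unlist(lapply(niches, function(nc) unlist(nc$lr_pairs))))
    gene_ids <- c(marker_ids, lr_genes)
    Gn <- length(gene_ids)
    sig <- matrix(0.05, K, Gn, dimnames = list(cell_types, gene_ids))
    for (k in seq_len(K)) {
      sig[k, sprintf("%s_mk%d", cell_types[k], seq_len(markers_per_type))] <- 1
    }
    if (length(lr_genes)) sig[, lr_genes] <- 0.2
    mu <- A %*% sig                         # spots x genes
    for (ii in seq_along(niches)) {
      nc <- niches[[ii]]
      gl <- unique(unlist(nc$lr_pairs))
      if (length(gl)) {
        fac <- 1 + (nc$elevation - 1) * kernels[[ii]]
        mu[, gl] <- mu[, gl] * fac
      }
    }
    lib <- rlnorm(n_spots, lib_size_meanlog, lib_size_sdlog)
    p <- mu / rowSums(mu)
    lam <- p * lib
    counts <- matrix(rpois(length(lam), lambda = as.vector(lam)),
                     nrow = n_spots, ncol = Gn,
                     dimnames = list(spots$spot_id, gene_ids))
    counts <- methods::as(Matrix::Matrix(t(counts), sparse = TRUE),
                          "CsparseMatrix")
    structure(
      list(spots = spots, abundance = A, counts = counts,
           gene_ids = gene_ids, lr_genes = lr_genes,
           params = list(n_spots = n_spots, cell_types = cell_types,
                         baseline_conc = baseline_conc, seed = seed,
                         niches = niches)),
      class = "spatial_map_sim"
    )
  })
}

#' Simulate an mIHC-style point pattern around niche objects
#'
#' Niche objects (e.g. vessels) are placed uniformly on the field; each
#' cell picks a niche object at random and is placed at a gamma-distributed
#' distance (mean `target_mean_distance`, shape `shape`) in a uniformly
#' random bearing, then clipped to the field. The gamma kernel gives a
#' strictly positive, unimodal distance distribution with controllable
#' mean and spread. The pre-clipping generating distances are kept in
#' `attr(x, "generating_distances")` for validation.
#'
#' @param n_niche_objects Number of niche objects (>= 1).
#' @param n_cells Number of cells (0 allowed).
#' @param target_mean_distance Mean generating distance, micrometres, > 0.
#' @param field `c(width, height)` of the field in micrometres; must be
#'   large enough to hold the target distance. The default 5000 x 5000 um
#'   emulates a whole-slide region in which niche objects (e.g. vessels)
#'   are sparse, so a cell's nearest niche object is almost always the one
#'   it was placed around.
#' @param seed Integer seed.
#' @param shape Gamma shape (default 4, i.e. sd = mean / 2).
#' @param niche_label,cell_label Phenotype labels used in the output.
#' @return data.frame of class `"point_pattern"` with columns `cell_id`,
#'   `phenotype`, `x_um`, `y_um`, `is_niche`.
#' @examples
#' pp <- simulate_point_pattern(5, 100, 120, seed = 1)
#' table(pp$phenotype)
#' @export
simulate_point_pattern <- function(n_niche_objects, n_cells,
                                   target_mean_distance,
                                   field = c(5000, 5000), seed = 1L,
                                   shape = 4,
                                   niche_label = "niche_object",
                                   cell_label = "cell") {
  stopifnot(
    "n_niche_objects must be >= 1" = n_niche_objects >= 1L,
    "n_cells must be >= 0" = n_cells >= 0L,
    "target_mean_distance must be > 0" = target_mean_distance > 0,
    "field must be c(width, height)" = length(field) == 2L && all(field > 0)
  )
  if (min(field) < 2 * target_mean_distance) {
    stop("field too small for target_mean_distance")
  }
  with_seed(seed, {
    ox <- runif(n_niche_objects, 0, field[1])
    oy <- runif(n_niche_objects, 0, field[2])
    if (n_cells > 0) {
      pick <- sample.int(n_niche_objects, n_cells, replace = TRUE)
      d <- rgamma(n_cells, shape = shape,
                  rate = shape / target_mean_distance)
      theta <- runif(n_cells, 0, 2 * pi)
      cx <- pmin(pmax(ox[pick] + d * cos(theta), 0), field[1])
      cy <- pmin(pmax(oy[pick] + d * sin(theta), 0), field[2])
    } else {
      d <- numeric(0)
      cx <- cy <- numeric(0)
    }
    out <- data.frame(
      cell_id = c(sprintf("obj_%03d", seq_len(n_niche_objects)),
                  if (n_cells > 0) sprintf("cell_%04d", seq_len(n_cells))),
      phenotype = c(rep(niche_label, n_niche_objects),
                    rep(cell_label, n_cells)),
      x_um = c(ox, cx), y_um = c(oy, cy),
      is_niche = c(rep(TRUE, n_niche_objects), rep(FALSE, n_cells)),
      stringsAsFactors = FALSE
    )
    class(out) <- c("point_pattern", "data.frame")
    attr(out, "generating_distances") <- d
    attr(out, "field") <- field
    out
  })
}

#' Specify a synthetic patient cohort
#'
#' @param n_per_arm Patients per arm (single value or named per arm).
#' @param arms Arm labels (default the trial's two arms: mono-immunotherapy
#'   `"Im"` and immunochemotherapy `"ImC"`).
#' @param response_rates Named per-arm responder probability in `[0, 1]`.
#' @param cell_types Cell-type names.
#' @param baseline_conc Symmetric Dirichlet concentration of the baseline
#'   fractions (default 8: realistic modest between-patient variability).
#' @param effects Mean pre-to-post fraction shifts: a data.frame with
#'   columns `cell_type`, `shift`, and optional `arm` / `response` columns
#'   (NA = applies to all); or a named numeric vector of per-type shifts
#'   applied to every arm/response.
#' @param noise_sd Gaussian sd added per type to the post fractions
#'   (>= 0). Post fractions are clipped at 0 and renormalized to the
#'   simplex.
#' @return Object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_arm = 34L,
                        arms = c("Im", "ImC"),
                        response_rates = c(Im = 0.147, ImC = 0.764),
                        cell_types = default_cell_types(),
                        baseline_conc = 8,
                        effects = NULL,
                        noise_sd = 0.02) {
  if (length(n_per_arm) == 1L) {
    n_per_arm <- stats::setNames(rep(n_per_arm, length(arms)), arms)
  }
  stopifnot(
    all(arms %in% names(n_per_arm)),
    all(arms %in% names(response_rates)),
    all(response_rates >= 0 & response_rates <= 1),
    noise_sd >= 0, baseline_conc > 0, length(cell_types) >= 2L
  )
  effects <- normalize_effects(effects, cell_types)
  structure(list(n_per_arm = n_per_arm, arms = arms,
                 response_rates = response_rates, cell_types = cell_types,
                 baseline_conc = baseline_conc, effects = effects,
                 noise_sd = noise_sd),
            class = "cohort_spec")
}

normalize_effects <- function(effects, cell_types) {
  if (is.null(effects)) {
    return(data.frame(cell_type = character(), arm = character(),
                      response = character(), shift = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (is.numeric(effects) && !is.null(names(effects))) {
    effects <- data.frame(cell_type = names(effects), arm = NA_character_,
                          response = NA_character_, shift = unname(effects),
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(effects),
            all(c("cell_type", "shift") %in% names(effects)))
  if (is.null(effects$arm)) effects$arm <- NA_character_
  if (is.null(effects$response)) effects$response <- NA_character_
  unknown <- setdiff(effects$cell_type, cell_types)
  if (length(unknown)) {
    stop("effect on unknown cell type(s): ", paste(unknown, collapse = ", "))
  }
  effects[c("cell_type", "arm", "response", "shift")]
}

#' Simulate a paired pre/post cohort of cell-type fractions
#'
#' Per patient: baseline fractions ~ symmetric Dirichlet; post fractions =
#' baseline + the matching effect shifts + Gaussian noise, clipped at 0
#' and renormalized to sum 1; responder label drawn from the arm's
#' response rate. With zero effect and zero noise the post row equals the
#' baseline row exactly.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return data.frame (CohortTable): one row per (patient, timepoint) with
#'   columns `patient`, `arm`, `timepoint` (`"baseline"` / `"post"`),
#'   `response` (`"responder"` / `"non_responder"`), then one numeric
#'   fraction column per cell type.
#' @examples
#' ct <- simulate_cohort(cohort_spec(n_per_arm = 4), seed = 1)
#' head(ct)
#' @export
simulate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  K <- length(spec$cell_types)
  with_seed(seed, {
    rows <- list()
    pid <- 0L
    for (arm in spec$arms) {
      n <- spec$n_per_arm[[arm]]
      for (i in seq_len(n)) {
        pid <- pid + 1L
        patient <- sprintf("P%03d", pid)
        response <- if (runif(1) < spec$response_rates[[arm]]) {
          "responder"
        } else {
          "non_responder"
        }
        g <- rgamma(K, shape = spec$baseline_conc)
        pre <- g / sum(g)
        shift <- unname(effect_shift(spec$effects, spec$cell_types,
                                     arm, response))
        if (all(shift == 0) && spec$noise_sd == 0) {
          post <- pre
        } else {
          post <- pre + shift + rnorm(K, 0, spec$noise_sd)
          post <- pmax(post, 0)
          if (sum(post) == 0) post <- pre else post <- post / sum(post)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          patient = patient, arm = arm,
          timepoint = c("baseline", "post"),
          response = response,
          rbind(pre, post), row.names = NULL, stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    names(out)[5:(4 + K)] <- spec$cell_types
    rownames(out) <- NULL
    out
  })
}

effect_shift <- function(effects, cell_types, arm, response) {
  shift <- stats::setNames(numeric(length(cell_types)), cell_types)
  if (!nrow(effects)) return(shift)
  hit <- (is.na(effects$arm) | effects$arm == arm) &
    (is.na(effects$response) | effects$response == response)
  for (r in which(hit)) {
    shift[effects$cell_type[r]] <- shift[effects$cell_type[r]] +
      effects$shift[r]
  }
  shift
}
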