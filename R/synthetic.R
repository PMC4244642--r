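#' Deterministic block atlas for phantoms
#'
#' Tiles the interior of the grid (leaving a one-voxel background margin)
#' with near-equal rectangular blocks and labels the first `n_regions` of
#' them 1..n_regions; remaining blocks, if any, stay background. The tiling
#' is a pure function of `shape` and `n_regions`, so the same arguments
#' always give the same label grid.
#'
#' @param shape Integer grid dimensions, length 3.
#' @param n_regions Number of regions (>= 1) that must fit in the grid.
#' @param voxel_size_mm Voxel size recorded on the atlas (default 1.5 mm,
#'   the resolution of segmented tissue maps this generator emulates).
#' @return An [atlas_parcellation()].
#' @export
make_atlas <- function(shape, n_regions, voxel_size_mm = 1.5) {
  shape <- as.integer(rep_len(shape, 3L))
  n_regions <- as.integer(n_regions)
  stopifnot(n_regions >= 1L)
  inner <- shape - 2L
  if (any(inner < 1L)) abort("grid too small for a background margin")
  splits <- c(1L, 1L, 1L)
  while (prod(splits) < n_regions) {
    block <- inner / splits
    ax <- which.max(block)
    if (block[ax] < 2) abort("too many regions for this grid")
    splits[ax] <- splits[ax] + 1L
  }
  cuts <- lapply(1:3, function(a) {
    bounds <- 1L + round(seq(0, inner[a], length.out = splits[a] + 1L))
    lapply(seq_len(splits[a]), function(b) (bounds[b] + 1L):bounds[b + 1L])
  })
  labels <- array(0L, dim = shape)
  lab <- 0L
  for (kz in seq_len(splits[3])) for (ky in seq_len(splits[2])) for (kx in seq_len(splits[1])) {
    lab <- lab + 1L
    if (lab > n_regions) break
    labels[cuts[[1]][[kx]], cuts[[2]][[ky]], cuts[[3]][[kz]]] <- lab
  }
  if (any(tabulate(labels[labels > 0L], n_regions) == 0L)) {
    abort("too many regions for this grid")
  }
  atlas_parcellation(labels, voxel_size_mm = voxel_size_mm)
}

#' Phantom generator configuration
#'
#' Defaults describe the standard phantom: a 24^3 grid at 1.5 mm parcelled
#' into 8 regions, 240 labeled subjects at a balanced class prior, regional
#' gray-matter baseline 0.6, atrophy effect 0.25 with voxel noise 0.05, and
#' six affected regions whose atrophy indicators are coupled through two
#' dependency chains (1 -> 2 -> 3 and 4 -> 5 -> 6). In AD subjects a root
#' affected region atrophies with probability `p_root`; a child atrophies
#' with probability `p_child_hi` if any dependency parent is atrophied and
#' `p_child_lo` otherwise. In NC subjects every affected region atrophies
#' independently at the `p_baseline` rate. MCI converters follow the AD
#' atrophy process with the effect size scaled by `mci_effect_scale`.
#'
#' @param shape,n_regions,voxel_size_mm Atlas geometry ([make_atlas()]).
#' @param n Number of labeled (NC/AD) subjects.
#' @param n_mci Number of MCI-converter subjects (validation only).
#' @param class_prior Probability a labeled subject is AD.
#' @param affected Region ids subject to class-dependent atrophy.
#' @param dependency Two-column data frame of directed atrophy dependencies
#'   among affected regions (must be acyclic); `NULL` for conditionally
#'   independent atrophy at rate `p_root` in every affected region.
#' @param p_root,p_child_hi,p_child_lo,p_baseline Atrophy probabilities (see
#'   above).
#' @param baseline_gm,delta_gm,baseline_wm,delta_wm Mean tissue probability
#'   in regions and its reduction under atrophy, per tissue.
#' @param sigma Voxel-wise Gaussian noise standard deviation.
#' @param mci_effect_scale Multiplier on `delta_gm`/`delta_wm` for MCI
#'   converters.
#' @param seed Master seed; each subject draws from its own substream so a
#'   larger cohort extends, never perturbs, a smaller one.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(24L, 24L, 24L), n_regions = 8L,
                           voxel_size_mm = 1.5, n = 240L, n_mci = 0L,
                           class_prior = 0.5, affected = 1:6,
                           dependency = data.frame(from = c(1L, 2L, 4L, 5L),
                                                   to = c(2L, 3L, 5L, 6L)),
                           p_root = 0.8, p_child_hi = 0.9, p_child_lo = 0.1,
                           p_baseline = 0.05,
                           baseline_gm = 0.6, delta_gm = 0.25,
                           baseline_wm = 0.6, delta_wm = 0.1,
                           sigma = 0.05, mci_effect_scale = 0.7, seed = 1L) {
  stopifnot(delta_gm > 0, delta_gm < 1, sigma >= 0, class_prior > 0,
            class_prior < 1, all(affected %in% seq_len(n_regions)))
  for (p in c(p_root, p_child_hi, p_child_lo, p_baseline)) {
    stopifnot(p >= 0, p <= 1)
  }
  if (!is.null(dependency) && nrow(dependency) > 0) {
    stopifnot(all(unlist(dependency) %in% affected))
    midx <- match(affected, affected)
    adj <- matrix(FALSE, length(affected), length(affected))
    adj[cbind(match(dependency$from, affected), match(dependency$to, affected))] <- TRUE
    if (!is_acyclic(adj)) abort("atrophy dependency graph must be acyclic")
  }
  structure(as.list(environment())[c(
    "shape", "n_regions", "voxel_size_mm", "n", "n_mci", "class_prior",
    "affected", "dependency", "p_root", "p_child_hi", "p_child_lo",
    "p_baseline", "baseline_gm", "delta_gm", "baseline_wm", "delta_wm",
    "sigma", "mci_effect_scale", "seed")], class = "phantom_config")
}

# Ancestral sampling of the atrophy indicators for one AD-like subject.
sample_indicators <- function(config) {
  aff <- config$affected
  ind <- setNames(integer(length(aff)), aff)
  dep <- config$dependency
  order_ids <- if (is.null(dep) || nrow(dep) == 0) aff else {
    adj <- matrix(FALSE, length(aff), length(aff))
    adj[cbind(match(dep$from, aff), match(dep$to, aff))] <- TRUE
    aff[topological_order(adj)]
  }
  for (r in order_ids) {
    parents <- if (is.null(dep)) integer(0) else dep$from[dep$to == r]
    p <- if (length(parents) == 0) config$p_root
         else if (any(ind[as.character(parents)] == 1L)) config$p_child_hi
         else config$p_child_lo
    ind[as.character(r)] <- rbinom(1L, 1L, p)
  }
  ind
}

#' Simulate a phantom cohort of tissue-probability volumes
#'
#' Emulates segmented, atlas-aligned MRI output: per subject, a class is
#' drawn from the prior, regional atrophy indicators are sampled by
#' ancestral sampling of the dependency graph (AD and MCI converters) or at
#' independent baseline rates (NC), and each tissue volume is built as
#' `clip(baseline - delta * indicator + N(0, sigma), 0, 1)` inside atlas
#' regions, 0 in the background. All randomness flows from the master seed
#' through per-subject substreams.
#'
#' @param config A [phantom_config()].
#' @return A list of class `phantom_dataset`: `subjects` (tibble with
#'   `subject_id`, `label`, `y`, `atrophy` list-column of named indicator
#'   vectors, and `gm` / `wm` list-columns of 3-D arrays), `atlas`, and
#'   `config`.
#' @export
simulate_subjects <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  atlas <- make_atlas(config$shape, config$n_regions, config$voxel_size_mm)
  region_mask <- atlas$labels > 0L
  aff_mask <- lapply(config$affected, function(id) atlas$labels == id)
  names(aff_mask) <- config$affected

  n_total <- config$n + config$n_mci
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    set.seed(substream_seed(config$seed, i))
    is_mci <- i > config$n
    if (is_mci) {
      label <- "MCI_C"; y <- NA_integer_
      ind <- sample_indicators(config)
      scale <- config$mci_effect_scale
    } else {
      y <- if (runif(1) < config$class_prior) 1L else -1L
      label <- if (y == 1L) "AD" else "NC"
      ind <- if (y == 1L) sample_indicators(config) else
        setNames(rbinom(length(config$affected), 1L, config$p_baseline),
                 config$affected)
      scale <- 1
    }
    make_tissue <- function(baseline, delta) {
      vol <- array(0, dim = config$shape)
      vol[region_mask] <- baseline + rnorm(sum(region_mask), 0, config$sigma)
      for (id in names(aff_mask)) {
        if (ind[[id]] == 1L) {
          vol[aff_mask[[id]]] <- vol[aff_mask[[id]]] - delta * scale
        }
      }
      vol[] <- pmin(pmax(vol, 0), 1)
      vol
    }
    rows[[i]] <- tibble::tibble(
      subject_id = sprintf("S%04d", i), label = label, y = y,
      atrophy = list(ind),
      gm = list(make_tissue(config$baseline_gm, config$delta_gm)),
      wm = list(make_tissue(config$baseline_wm, config$delta_wm))
    )
  }
  structure(list(subjects = purrr::list_rbind(rows), atlas = atlas,
                 config = config),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d subjects (%d MCI-c), grid %s, %d regions\n",
              nrow(x$subjects), x$config$n_mci,
              paste(x$config$shape, collapse = "x"), x$config$n_regions))
  invisible(x)
}

#' Write a phantom dataset to disk
#'
#' Emits per-subject NIfTI volumes, the atlas NIfTI, a manifest CSV, a
#' region-table CSV, and a YAML snapshot of the generator configuration.
#'
#' @param dataset A `phantom_dataset`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_phantom <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(dataset$atlas, file.path(dir, "atlas.nii.gz"))
  readr::write_csv(dataset$atlas$region_table, file.path(dir, "regions.csv"))
  rows <- dataset$subjects
  manifest <- purrr::pmap(list(rows$subject_id, rows$label, rows$gm, rows$wm),
    function(id, lab, gm, wm) {
      gm_path <- file.path(dir, paste0(id, "_gm.nii.gz"))
      wm_path <- file.path(dir, paste0(id, "_wm.nii.gz"))
      write_volume(tissue_image(gm, id, "GM", label = lab,
                                voxel_size_mm = dataset$atlas$voxel_size_mm),
                   gm_path)
      write_volume(tissue_image(wm, id, "WM", label = lab,
                                voxel_size_mm = dataset$atlas$voxel_size_mm),
                   wm_path)
      tibble::tibble(subject_id = id, gm_path = gm_path, wm_path = wm_path,
                     csf_path = NA_character_, label = lab)
    }) |> purrr::list_rbind()
  manifest_path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path)
  cfg <- dataset$config
  cfg$dependency <- if (!is.null(cfg$dependency)) as.list(as.data.frame(cfg$dependency))
  yaml::write_yaml(cfg, file.path(dir, "generator.yaml"))
  invisible(manifest_path)
}

#' Sample outcome vectors from a ground-truth network
#'
#' Ancestral sampling: the class is drawn first from the prior, then each
#' component node in topological order from its conditional table. Used to
#' plant known structures for testing structure and parameter recovery.
#'
#' @param model An `sc_bn` (e.g. from [bn_model()]).
#' @param n Number of outcome vectors.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Outcome tibble: `subject_id`, `y`, `z_<region_id>` columns.
#' @export
simulate_outcomes <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "sc_bn"))
  if (!is.null(seed)) set.seed(seed)
  st <- model$structure
  m <- length(st$region_ids)
  ord <- topological_order(st$adj)
  y <- ifelse(runif(n) < model$prior_pos, 1L, -1L)
  z <- matrix(0L, n, m)
  for (j in ord) {
    cp <- model$cpts[[j]]
    zpa <- if (length(cp$parents) > 0) z[, cp$parents, drop = FALSE] else NULL
    p1 <- cp$p1[config_index(y, zpa)]
    z[, j] <- ifelse(runif(n) < p1, 1L, -1L)
  }
  out <- tibble::tibble(subject_id = sprintf("S%04d", seq_len(n)), y = y)
  for (j in seq_len(m)) out[[zcol(st$region_ids[j])]] <- z[, j]
  out
}
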