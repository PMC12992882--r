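#' Split a binary vessel mask at the midsagittal plane
#'
#' Partitions the mask by the first-axis midpoint of the (canonical,
#' left-to-right) template grid: voxels with first-axis index `<= nx/2` go
#' left, the rest right. The two outputs partition the input exactly; the
#' basilar artery and other midline-straddling vessels are attributed by
#' this axis-plane rule.
#'
#' @param vessels Binary `label_volume` in canonical orientation.
#' @return Named list of two binary `label_volume`s: `left`, `right`.
#' @export
split_hemispheres <- function(vessels) {
  stopifnot(inherits(vessels, "label_volume"))
  if (!any(vessels$data != 0L)) stop("cannot split an empty mask")
  dims <- dim(vessels$data)
  midx <- dims[1] %/% 2L
  xs <- array(rep(seq_len(dims[1]), times = prod(dims[2:3])), dims)
  left <- vessels$data
  left[xs > midx] <- 0L
  right <- vessels$data
  right[xs <= midx] <- 0L
  mk <- function(d) label_volume(array(as.integer(d != 0L), dims),
                                 spacing = vessels$spacing,
                                 affine = vessels$affine,
                                 label_map = c(vessel = 1L))
  list(left = mk(left), right = mk(right))
}

#' Merge circle-of-Willis segment labels to the 5-label scheme
#'
#' MCA and ICA keep distinct per-side labels; ACA, PCA, Acom, Pcom and BA
#' are merged into a single communicating-vessel class, giving five labels
#' total (MCA-L, MCA-R, ICA-L, ICA-R, communicating).
#'
#' @param cow Multilabel `label_volume` whose label names are a subset of
#'   MCA-L/MCA-R/ICA-L/ICA-R/ACA/PCA/Acom/Pcom/BA (or already the 5-label
#'   scheme, in which case this is the identity).
#' @param alias Optional label-alias table: named character vector mapping
#'   non-canonical label names in `cow$label_map` to canonical segment
#'   names, e.g. `c("A3" = "ACA")`.
#' @return A `label_volume` with label names MCA-L, MCA-R, ICA-L, ICA-R,
#'   communicating.
#' @export
merge_cow_labels <- function(cow, alias = NULL) {
  stopifnot(inherits(cow, "label_volume"))
  target <- c("MCA-L" = 1L, "MCA-R" = 2L, "ICA-L" = 3L, "ICA-R" = 4L,
              "communicating" = 5L)
  comm <- c("ACA", "PCA", "Acom", "Pcom", "BA")
  nm <- names(cow$label_map)
  if (!is.null(alias)) nm <- ifelse(nm %in% names(alias), alias[nm], nm)
  if (setequal(nm, names(target)) || all(nm %in% names(target))) {
    # already merged: relabel ids to the canonical 5-label ids
    map_to <- target[nm]
  } else {
    known <- c(names(target)[1:4], comm)
    bad <- setdiff(nm, known)
    if (length(bad) > 0) {
      stop("unknown CoW label(s): ", paste(bad, collapse = ", "),
           " (ids ", paste(cow$label_map[nm %in% bad], collapse = ", "), ")")
    }
    map_to <- ifelse(nm %in% comm, target[["communicating"]], target[nm])
  }
  lut <- integer(max(cow$label_map) + 1L) # id -> merged id, offset by 1
  lut[cow$label_map + 1L] <- as.integer(map_to)
  out <- array(lut[cow$data + 1L], dim(cow$data))
  label_volume(out, spacing = cow$spacing, affine = cow$affine,
               label_map = target)
}

#' Build per-side composite MCA territory masks from a territory atlas
#'
#' Keeps only MCA-related subregions (label names containing `"M<k>-terr"`)
#' and merges them into one binary composite per side; non-MCA territories
#' (ACA-terr, PCA-terr, ...) are excluded.
#'
#' @param territory_atlas Multilabel `label_volume` whose label names end in
#'   `-L` / `-R` and whose MCA subregions match `^M[0-9]+-terr`.
#' @return Named list of binary `label_volume`s `mca_terr_L`, `mca_terr_R`.
#' @export
build_mca_composite <- function(territory_atlas) {
  stopifnot(inherits(territory_atlas, "label_volume"))
  nm <- names(territory_atlas$label_map)
  mca <- grepl("^M[0-9]+-terr", nm)
  if (!any(mca) ||
      !any(territory_atlas$data %in% territory_atlas$label_map[mca])) {
    stop("atlas contains no MCA subregions (labels 'M<k>-terr-L/R')")
  }
  out <- list()
  for (side in c("L", "R")) {
    ids <- territory_atlas$label_map[mca & endsWith(nm, paste0("-", side))]
    comp <- array(as.integer(territory_atlas$data %in% ids),
                  dim(territory_atlas$data))
    if (sum(comp) == 0L) {
      warning("side ", side, " has no MCA territory voxels; composite is empty")
    }
    out[[paste0("mca_terr_", side)]] <- label_volume(
      comp, spacing = territory_atlas$spacing, affine = territory_atlas$affine,
      label_map = stats::setNames(1L, paste0("mca_terr_", side)))
  }
  out
}

#' Assemble the ROI set for one case under a model variant
#'
#' Variant A: the two hemispheric vessel-tree masks (`vessels_L`,
#' `vessels_R`). Variant B: the two composite MCA territories
#' (`mca_terr_L`, `mca_terr_R`). Variant C: seven ROIs -- hemispheric
#' vessel trees (`hemi_L`, `hemi_R`), per-side ICA and MCA from the merged
#' CoW mask (`ica_L`, `ica_R`, `mca_L`, `mca_R`) and the merged
#' communicating-vessel class (`communicating`).
#'
#' @param case A `phantom_case`, or any list with the masks the variant
#'   needs (`vessel_mask` for A/C, `territory_atlas` or `mca_territory` for
#'   B, `cow_mask` for C).
#' @param variant `"A"`, `"B"` or `"C"`.
#' @return An object of class `roi_set`: list with `case_id`, `variant`,
#'   `rois` (named list of binary `label_volume`s).
#' @export
assemble_rois <- function(case, variant = c("A", "B", "C")) {
  variant <- match.arg(variant)
  need <- function(field) {
    if (is.null(case[[field]])) {
      stop("variant ", variant, " requires mask '", field, "' but it is missing")
    }
    case[[field]]
  }
  rois <- switch(variant,
    A = {
      h <- split_hemispheres(need("vessel_mask"))
      list(vessels_L = h$left, vessels_R = h$right)
    },
    B = {
      atlas <- case$territory_atlas
      if (!is.null(atlas)) {
        build_mca_composite(atlas)
      } else {
        comp <- need("mca_territory")
        dims <- dim(comp$data)
        mk <- function(id, nm) label_volume(
          array(as.integer(comp$data == id), dims), spacing = comp$spacing,
          affine = comp$affine, label_map = stats::setNames(1L, nm))
        list(mca_terr_L = mk(1L, "mca_terr_L"), mca_terr_R = mk(2L, "mca_terr_R"))
      }
    },
    C = {
      h <- split_hemispheres(need("vessel_mask"))
      merged <- merge_cow_labels(need("cow_mask"))
      dims <- dim(merged$data)
      pick <- function(nm) {
        id <- merged$label_map[[nm]]
        label_volume(array(as.integer(merged$data == id), dims),
                     spacing = merged$spacing, affine = merged$affine,
                     label_map = stats::setNames(1L, nm))
      }
      list(hemi_L = h$left, hemi_R = h$right,
           ica_L = pick("ICA-L"), ica_R = pick("ICA-R"),
           mca_L = pick("MCA-L"), mca_R = pick("MCA-R"),
           communicating = pick("communicating"))
    }
  )
  structure(list(case_id = case$case_id %||% NA_character_,
                 variant = variant, rois = rois),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> variant %s, %d ROIs: %s\n", x$variant,
              length(x$rois), paste(names(x$rois), collapse = ", ")))
  invisible(x)
}

#' Read a label-alias table from a key=value text config
#'
#' Each non-comment line is `id_or_name = canonical_name`; used to accept
#' atlases/CoW masks whose segments arrive under non-canonical names (e.g.
#' `A3 = ACA`).
#'
#' @param path Text file path.
#' @return Named character vector (alias -> canonical name).
#' @export
read_label_aliases <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed alias line(s): ", paste(lines[bad], collapse = "; "))
  stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
}
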