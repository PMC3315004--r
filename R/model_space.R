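#' Enumerate the modulatory-coupling model space
#'
#' Builds the hypothesis space over which couplings are modulated by grip
#' force. The intrinsic (A) structure is fixed fully connected and the
#' driving input enters every left-hemisphere region, so models differ only
#' in their modulatory (B) masks. Eight families are formed by crossing the
#' hub M1 (left families 1-4, right families 5-8), the hemisphere of the
#' secondary motor areas involved (same as the hub, or opposite) and the
#' direction of the modulated connections (from hub to secondary areas, or
#' towards the hub). Within a family one model is created per non-empty
#' subset of the secondary areas crossed with three self-connection
#' variants: all areas in the model self-modulated, hub only, or secondary
#' area(s) only. With three secondary areas per hemisphere this yields
#' (2^3 - 1) * 3 = 21 models per family and 168 models in total.
#'
#' Family ids per hub follow the order (same hemisphere, from hub) = 1,
#' (same, to hub) = 2, (opposite, to hub) = 3, (opposite, from hub) = 4;
#' the family of models modulating connections from left M1 to the
#' contralateral secondary areas - the winning family of the hand-grip
#' study - is therefore family 4.
#'
#' @param regions a [region_set()]; needs one M1 per hemisphere and at
#'   least one secondary area per hemisphere.
#' @return A `model_space` object: list with `models` (list of `model_spec`
#'   objects), `families` (data.frame of family descriptors), `regions`,
#'   `n_models`.
#' @examples
#' sp <- enumerate_model_space()
#' sp$n_models                       # 168
#' nrow(sp$families)                 # 8
#' @export
enumerate_model_space <- function(regions = region_set()) {
  n <- regions$n
  hubs <- c(L = match("M1_L", regions$labels), R = match("M1_R", regions$labels))
  if (anyNA(hubs)) stop("configuration error: region set must contain M1_L and M1_R")
  sec <- list(L = which(regions$hemisphere == "L" & regions$area != "M1"),
              R = which(regions$hemisphere == "R" & regions$area != "M1"))
  if (any(lengths(sec) == 0)) {
    stop("configuration error: each hemisphere needs at least one secondary area")
  }

  variants <- data.frame(
    secondary_hemisphere = c("same", "same", "opposite", "opposite"),
    direction = c("from-hub", "to-hub", "to-hub", "from-hub"))
  families <- do.call(rbind, lapply(c("L", "R"), function(hb) {
    cbind(hub = paste0("M1_", hb), variants)
  }))
  families$family_id <- seq_len(nrow(families))

  a_mask <- matrix(1L, n, n, dimnames = list(regions$labels, regions$labels))
  c_mask <- matrix(0L, n, 2, dimnames = list(regions$labels,
                                             c("driving", "modulatory")))
  c_mask[regions$hemisphere == "L", 1] <- 1L

  subsets_of <- function(idx) {
    subs <- list()
    for (k in seq_along(idx)) {
      # combn() treats a scalar first argument as seq_len(); index into idx
      cmb <- utils::combn(seq_along(idx), k, simplify = FALSE)
      subs <- c(subs, lapply(cmb, function(sel) idx[sel]))
    }
    subs
  }

  models <- list()
  id <- 0L
  for (fi in seq_len(nrow(families))) {
    hub_hemi <- sub("^M1_", "", families$hub[fi])
    hub <- hubs[[hub_hemi]]
    sec_hemi <- if (families$secondary_hemisphere[fi] == "same") hub_hemi else
      setdiff(c("L", "R"), hub_hemi)
    from_hub <- families$direction[fi] == "from-hub"
    for (subset in subsets_of(sec[[sec_hemi]])) {
      for (selfvar in c("all", "hub", "secondary")) {
        id <- id + 1L
        b <- matrix(0L, n, n, dimnames = dimnames(a_mask))
        for (s in subset) {
          if (from_hub) b[s, hub] <- 1L else b[hub, s] <- 1L
        }
        self_regions <- switch(selfvar,
                               all = c(hub, subset),
                               hub = hub,
                               secondary = subset)
        b[cbind(self_regions, self_regions)] <- 1L
        models[[id]] <- structure(
          list(model_id = id, family_id = families$family_id[fi],
               a_mask = a_mask,
               b_masks = list(driving = matrix(0L, n, n, dimnames = dimnames(a_mask)),
                              modulatory = b),
               c_mask = c_mask,
               modulated = regions$labels[subset], self_variant = selfvar),
          class = "model_spec")
      }
    }
  }
  structure(list(models = models, families = families, regions = regions,
                 n_models = id),
            class = "model_space")
}

#' @export
print.model_space <- function(x, ...) {
  cat(sprintf("Model space: %d models in %d families over %d regions\n",
              x$n_models, nrow(x$families), x$regions$n))
  invisible(x)
}

#' Members of the winning family
#'
#' Returns the models of the family found to generalise best in the
#' hand-grip study: left M1 as hub, secondary motor areas in the opposite
#' (right) hemisphere, modulation directed from the hub to the secondary
#' areas (family 4).
#'
#' @param space a [enumerate_model_space()] object.
#' @return list of `model_spec` objects (21 with the default regions).
#' @export
winning_family_models <- function(space) {
  fam <- space$families
  fid <- fam$family_id[fam$hub == "M1_L" &
                         fam$secondary_hemisphere == "opposite" &
                         fam$direction == "from-hub"]
  Filter(function(mod) mod$family_id == fid, space$models)
}

#' @rdname winning_family_models
#' @details `maximal_model()` picks the member of a model list whose
#'   modulation subset includes all available secondary areas with the
#'   all-areas self variant (the generating model of the synthetic cohort).
#' @param models list of `model_spec` objects.
#' @export
maximal_model <- function(models) {
  nmod <- vapply(models, function(mod) length(mod$modulated), integer(1))
  cand <- models[nmod == max(nmod)]
  sv <- vapply(cand, function(mod) mod$self_variant, character(1))
  cand[[match("all", sv)]]
}

#' Map model ids to family ids
#'
#' @param space a `model_space`.
#' @return integer vector of family ids, one per model, named by model id.
#' @export
model_families <- function(space) {
  setNames(vapply(space$models, function(mod) mod$family_id, integer(1)),
           vapply(space$models, function(mod) mod$model_id, integer(1)))
}

#' Serialize or load a model space as JSON
#'
#' @param space a `model_space`.
#' @param path JSON file path.
#' @rdname model_space_io
#' @export
write_model_space <- function(space, path) {
  payload <- list(
    regions = space$regions$labels,
    families = space$families,
    models = lapply(space$models, function(mod) {
      list(model_id = mod$model_id, family_id = mod$family_id,
           a_mask = unname(mod$a_mask),
           b_masks = lapply(mod$b_masks, unname),
           c_mask = unname(mod$c_mask),
           modulated = mod$modulated, self_variant = mod$self_variant)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_space_io
#' @export
read_model_space <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE,
                                 simplifyMatrix = TRUE)
  regions <- region_set(payload$regions)
  nmask <- function(m) {
    m <- matrix(as.integer(m), regions$n,
                dimnames = list(regions$labels, regions$labels))
    m
  }
  models <- lapply(seq_len(nrow(payload$models)), function(i) {
    row <- payload$models[i, ]
    structure(list(
      model_id = row$model_id, family_id = row$family_id,
      a_mask = nmask(row$a_mask[[1]]),
      b_masks = list(driving = nmask(row$b_masks$driving[[1]]),
                     modulatory = nmask(row$b_masks$modulatory[[1]])),
      c_mask = matrix(as.integer(row$c_mask[[1]]), regions$n,
                      dimnames = list(regions$labels,
                                      c("driving", "modulatory"))),
      modulated = unlist(row$modulated), self_variant = row$self_variant),
      class = "model_spec")
  })
  structure(list(models = models, families = payload$families,
                 regions = regions, n_models = length(models)),
            class = "model_space")
}
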