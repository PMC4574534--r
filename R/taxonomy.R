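#' Arterial territories used by the whole-body reading scheme
#'
#' Territory labels, in the anatomical order used throughout the package:
#' head and neck, aorta, abdominal branch vessels, ilio-femoral axis, and the
#' popliteal/infrageniculate run-off.
#'
#' @return Character vector of the five territory codes.
#' @export
wbmra_territories <- function() {
  c("head_neck", "aorta", "abdominal", "iliofemoral", "runoff")
}

#' Default 31-segment arterial taxonomy
#'
#' The whole-body angiographic reading scheme divides the arterial tree, from
#' the distal internal carotid arteries to the calf vessels, into 31 vessel
#' segments grouped into five anatomical territories and acquired over four
#' imaging stations (1 head/neck/thorax, 2 abdomen/pelvis, 3 upper legs,
#' 4 lower legs). Territory sizes are 9 (head and neck), 3 (aorta),
#' 5 (abdominal), 6 (ilio-femoral) and 8 (run-off) segments.
#'
#' The territory structure and segment count follow the published reading
#' scheme; the individual segment *names* are a packaged convention, since the
#' scheme enumerates territories but not per-segment labels. A custom taxonomy
#' with the same shape can be supplied wherever a `taxonomy` argument is
#' accepted (see [read_taxonomy()]).
#'
#' @return A data.frame with columns `segment_id` (1--31), `name`,
#'   `territory` (one of [wbmra_territories()]) and `station` (1--4).
#' @examples
#' tax <- wbmra_taxonomy()
#' table(tax$territory)
#' @export
wbmra_taxonomy <- function() {
  tax <- data.frame(
    segment_id = 1:31,
    name = c(
      "right internal carotid artery", "left internal carotid artery",
      "right common carotid artery", "left common carotid artery",
      "right vertebral artery", "left vertebral artery",
      "right subclavian artery", "left subclavian artery",
      "brachiocephalic trunk",
      "thoracic aorta", "suprarenal abdominal aorta",
      "infrarenal abdominal aorta",
      "coeliac trunk", "superior mesenteric artery",
      "inferior mesenteric artery", "right renal artery", "left renal artery",
      "right common iliac artery", "left common iliac artery",
      "right external iliac artery", "left external iliac artery",
      "right common femoral artery", "left common femoral artery",
      "right superficial femoral artery", "left superficial femoral artery",
      "right popliteal artery", "left popliteal artery",
      "right anterior tibial artery", "left anterior tibial artery",
      "right posterior tibial artery", "left posterior tibial artery"
    ),
    territory = c(
      rep("head_neck", 9), rep("aorta", 3), rep("abdominal", 5),
      rep("iliofemoral", 6), rep("runoff", 8)
    ),
    station = c(
      rep(1L, 9),            # head/neck/thorax
      1L, 2L, 2L,            # aorta: thoracic then abdominal portions
      rep(2L, 5),            # abdominal branches
      2L, 2L, 2L, 2L, 3L, 3L,  # iliac then femoral
      3L, 3L, rep(4L, 6)     # thigh then calf run-off
    ),
    stringsAsFactors = FALSE
  )
  validate_taxonomy(tax)
  tax
}

#' Validate a segment taxonomy
#'
#' Checks the structural invariants every taxonomy must satisfy: exactly 31
#' segments with ids 1--31, each mapped to exactly one of the five territories
#' and one of stations 1--4, and territories jointly partitioning the segments.
#'
#' @param taxonomy A data.frame shaped like [wbmra_taxonomy()].
#' @return The taxonomy, invisibly, if valid; otherwise an error is raised.
#' @export
validate_taxonomy <- function(taxonomy) {
  stopifnot(is.data.frame(taxonomy))
  needed <- c("segment_id", "name", "territory", "station")
  missing_cols <- setdiff(needed, names(taxonomy))
  if (length(missing_cols)) {
    stop("taxonomy is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(taxonomy) != 31L || !setequal(taxonomy$segment_id, 1:31)) {
    stop("taxonomy must contain exactly segments 1-31, each once")
  }
  if (anyDuplicated(taxonomy$segment_id)) {
    stop("duplicate segment_id in taxonomy")
  }
  bad_terr <- setdiff(unique(taxonomy$territory), wbmra_territories())
  if (length(bad_terr)) {
    stop("unknown territory: ", paste(bad_terr, collapse = ", "))
  }
  if (length(unique(taxonomy$territory)) != 5L) {
    stop("all five territories must be represented")
  }
  if (!all(taxonomy$station %in% 1:4)) {
    stop("station must be an integer 1-4")
  }
  invisible(taxonomy)
}

#' Read a segment taxonomy from YAML or JSON
#'
#' Accepts either a list keyed by segment id mapping to
#' `{name, territory, station}` or a tabular records layout with those fields
#' plus `segment_id`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated taxonomy data.frame.
#' @export
read_taxonomy <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    stop("unsupported taxonomy format: .", ext)
  )
  if (is.null(names(raw))) {
    # records layout
    tax <- do.call(rbind, lapply(raw, function(r) {
      data.frame(
        segment_id = as.integer(r$segment_id), name = as.character(r$name),
        territory = as.character(r$territory), station = as.integer(r$station),
        stringsAsFactors = FALSE
      )
    }))
  } else {
    tax <- do.call(rbind, lapply(names(raw), function(id) {
      r <- raw[[id]]
      data.frame(
        segment_id = as.integer(id), name = as.character(r$name),
        territory = as.character(r$territory), station = as.integer(r$station),
        stringsAsFactors = FALSE
      )
    }))
  }
  tax <- tax[order(tax$segment_id), , drop = FALSE]
  rownames(tax) <- NULL
  validate_taxonomy(tax)
  tax
}

#' Write a taxonomy to YAML
#'
#' @param taxonomy A taxonomy data.frame.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  validate_taxonomy(taxonomy)
  out <- stats::setNames(
    lapply(seq_len(nrow(taxonomy)), function(i) {
      list(
        name = taxonomy$name[i],
        territory = taxonomy$territory[i],
        station = taxonomy$station[i]
      )
    }),
    as.character(taxonomy$segment_id)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
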