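# Species physiology: loading, validation, writing, allometric scaling.

#' Organ compartments of the PBK model
#'
#' The six perfused organ compartments; together with the central arterial
#' and venous blood pools they make up the eight-compartment circulatory
#' topology. `rest_of_body` closes the mass balance with the residual volume
#' and residual cardiac output.
#'
#' @format Character vector of organ identifiers.
#' @export
PBK_ORGANS <- c("lung", "liver", "spleen", "kidney", "heart", "rest_of_body")

#' Construct a species physiology object
#'
#' Bundles the species-specific physiological parameters the PBK model needs:
#' body weight, central arterial/venous blood pool volumes, cardiac output,
#' and per-organ total volume, vascular (blood) volume and perfusing blood
#' flow. For the liver, `blood_flow` is the hepatic-artery flow; the portal
#' inflow is represented by the spleen's venous outflow draining into the
#' liver (see [build_rate_matrix()]).
#'
#' @param species Species label (e.g. `"mouse"`).
#' @param body_weight Body weight in kg.
#' @param arterial_blood_volume,venous_blood_volume Central blood pool
#'   volumes in L (excludes blood resident in organ vascular beds).
#' @param cardiac_output Total cardiac output in L/h.
#' @param organs A data frame with columns `name`, `total_volume` (L),
#'   `vascular_volume` (L) and `blood_flow` (L/h), one row per entry of
#'   [PBK_ORGANS].
#' @return An object of class `species_physiology`.
#' @export
species_physiology <- function(species, body_weight, arterial_blood_volume,
                               venous_blood_volume, cardiac_output, organs) {
  organs <- as.data.frame(organs, stringsAsFactors = FALSE)
  phys <- structure(
    list(
      species = as.character(species),
      body_weight = as.numeric(body_weight),
      arterial_blood_volume = as.numeric(arterial_blood_volume),
      venous_blood_volume = as.numeric(venous_blood_volume),
      cardiac_output = as.numeric(cardiac_output),
      organs = organs
    ),
    class = "species_physiology"
  )
  validate_species_physiology(phys)
}

#' Validate a species physiology object
#'
#' Checks positivity of all volumes and flows, that every organ's vascular
#' volume is smaller than its total volume, that the organ set is exactly
#' [PBK_ORGANS], that the lung carries total cardiac output, that the
#' systemic organ flows (hepatic artery + spleen + kidney + heart +
#' rest-of-body) sum to cardiac output within 1%, and that total volume does
#' not exceed body weight at density 1 kg/L.
#'
#' @param phys A `species_physiology` object.
#' @return `phys`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_species_physiology <- function(phys) {
  stopifnot(inherits(phys, "species_physiology"))
  scal <- c(body_weight = phys$body_weight,
            arterial_blood_volume = phys$arterial_blood_volume,
            venous_blood_volume = phys$venous_blood_volume,
            cardiac_output = phys$cardiac_output)
  if (any(!is.finite(scal)) || any(scal <= 0)) {
    bad <- names(scal)[!is.finite(scal) | scal <= 0][1]
    stop("physiology field '", bad, "' must be a positive number", call. = FALSE)
  }
  org <- phys$organs
  needed <- c("name", "total_volume", "vascular_volume", "blood_flow")
  if (!all(needed %in% names(org))) {
    stop("organ table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(org$name, PBK_ORGANS) || anyDuplicated(org$name)) {
    stop("organ set must be exactly {", paste(PBK_ORGANS, collapse = ", "),
         "}", call. = FALSE)
  }
  num <- as.matrix(org[, c("total_volume", "vascular_volume", "blood_flow")])
  if (any(!is.finite(num)) || any(num <= 0)) {
    i <- which(!is.finite(num) | num <= 0, arr.ind = TRUE)[1, ]
    stop("organ '", org$name[i[1]], "' field '", colnames(num)[i[2]],
         "' must be a positive number", call. = FALSE)
  }
  bad_vasc <- org$vascular_volume >= org$total_volume
  if (any(bad_vasc)) {
    stop("vascular_volume must be < total_volume for organ '",
         org$name[which(bad_vasc)[1]], "'", call. = FALSE)
  }
  # lung in series: carries total cardiac output
  q_lung <- org$blood_flow[org$name == "lung"]
  if (abs(q_lung - phys$cardiac_output) > 0.01 * phys$cardiac_output) {
    stop("lung blood flow must equal cardiac output (pulmonary circulation ",
         "is in series)", call. = FALSE)
  }
  systemic <- setdiff(PBK_ORGANS, "lung")
  q_sum <- sum(org$blood_flow[org$name %in% systemic])
  if (abs(q_sum - phys$cardiac_output) > 0.01 * phys$cardiac_output) {
    stop(sprintf(paste0("systemic organ flows (%.4g L/h) must sum to cardiac",
                        " output (%.4g L/h) within 1%%"),
                 q_sum, phys$cardiac_output), call. = FALSE)
  }
  total_vol <- phys$arterial_blood_volume + phys$venous_blood_volume +
    sum(org$total_volume)
  if (total_vol > phys$body_weight * (1 + 1e-9)) {
    stop("sum of compartment volumes exceeds body weight at density 1 kg/L",
         call. = FALSE)
  }
  invisible(phys)
}

#' Load a species physiology
#'
#' Loads one of the bundled reference physiologies (`"mouse"`, `"rat"`,
#' `"human"`, transcribed from the standard physiological parameter
#' compilations; see the package vignette) or a user-supplied YAML file in
#' the same dialect, and validates it.
#'
#' @param source Species label of a bundled physiology, or path to a YAML
#'   file with keys `species`, `body_weight_kg`, `cardiac_output_L_per_h`,
#'   `arterial_blood_volume_L`, `venous_blood_volume_L` and an `organs`
#'   mapping with `total_volume_L`, `vascular_volume_L`,
#'   `blood_flow_L_per_h` per organ. Units fixed: kg, L, L/h.
#' @return A validated `species_physiology`.
#' @examples
#' mouse <- load_species_physiology("mouse")
#' mouse$cardiac_output
#' @export
load_species_physiology <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  bundled <- c("mouse", "rat", "human")
  if (source %in% bundled) {
    path <- system.file("extdata", "physiology", paste0(source, ".yaml"),
                        package = "mscpbk", mustWork = TRUE)
  } else if (file.exists(source)) {
    path <- source
  } else {
    stop("unknown species '", source, "' (bundled: ",
         paste(bundled, collapse = ", "), ") and no such file", call. = FALSE)
  }
  doc <- yaml::read_yaml(path)
  required <- c("species", "body_weight_kg", "cardiac_output_L_per_h",
                "arterial_blood_volume_L", "venous_blood_volume_L", "organs")
  miss <- setdiff(required, names(doc))
  if (length(miss) > 0) {
    stop("physiology file is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  org_names <- names(doc$organs)
  organs <- data.frame(
    name = org_names,
    total_volume = vapply(doc$organs, function(o) as.numeric(o$total_volume_L %||% NA_real_), 0),
    vascular_volume = vapply(doc$organs, function(o) as.numeric(o$vascular_volume_L %||% NA_real_), 0),
    blood_flow = vapply(doc$organs, function(o) as.numeric(o$blood_flow_L_per_h %||% NA_real_), 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  species_physiology(
    species = doc$species,
    body_weight = doc$body_weight_kg,
    arterial_blood_volume = doc$arterial_blood_volume_L,
    venous_blood_volume = doc$venous_blood_volume_L,
    cardiac_output = doc$cardiac_output_L_per_h,
    organs = organs
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a species physiology to a YAML file
#'
#' Emits the same dialect [load_species_physiology()] reads. Numbers are
#' written with 17 significant digits so a write/read round trip reproduces
#' every double bit-exactly.
#'
#' @param phys A `species_physiology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_species_physiology <- function(phys, path) {
  validate_species_physiology(phys)
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    "# Species physiology for the MSC PBK model.",
    "# Units: body_weight_kg [kg], volumes [L], flows [L/h].",
    paste0("species: ", phys$species),
    paste0("body_weight_kg: ", num(phys$body_weight)),
    paste0("cardiac_output_L_per_h: ", num(phys$cardiac_output)),
    paste0("arterial_blood_volume_L: ", num(phys$arterial_blood_volume)),
    paste0("venous_blood_volume_L: ", num(phys$venous_blood_volume)),
    "organs:"
  )
  org <- phys$organs
  for (i in seq_len(nrow(org))) {
    lines <- c(lines,
      paste0("  ", org$name[i], ":"),
      paste0("    total_volume_L: ", num(org$total_volume[i])),
      paste0("    vascular_volume_L: ", num(org$vascular_volume[i])),
      paste0("    blood_flow_L_per_h: ", num(org$blood_flow[i]))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Allometrically rescale a physiology to a new body weight
#'
#' Volumes scale proportionally with body weight; blood flows (and cardiac
#' output) scale with the standard allometric exponent on the weight ratio
#' (default 0.75). Supports crude scale-up of a calibrated rodent model to a
#' different body size; for cross-species prediction prefer the bundled
#' species files.
#'
#' @param base A `species_physiology`.
#' @param body_weight Target body weight in kg.
#' @param flow_exponent Allometric exponent applied to flows (default 0.75).
#' @return A rescaled, validated `species_physiology`.
#' @export
scale_physiology <- function(base, body_weight, flow_exponent = 0.75) {
  validate_species_physiology(base)
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0) {
    stop("body_weight must be a positive number", call. = FALSE)
  }
  f <- body_weight / base$body_weight
  organs <- base$organs
  organs$total_volume <- organs$total_volume * f
  organs$vascular_volume <- organs$vascular_volume * f
  organs$blood_flow <- organs$blood_flow * f^flow_exponent
  species_physiology(
    species = base$species,
    body_weight = body_weight,
    arterial_blood_volume = base$arterial_blood_volume * f,
    venous_blood_volume = base$venous_blood_volume * f,
    cardiac_output = base$cardiac_output * f^flow_exponent,
    organs = organs
  )
}

#' @export
print.species_physiology <- function(x, ...) {
  cat(sprintf("<species_physiology> %s: %.4g kg, CO %.4g L/h\n",
              x$species, x$body_weight, x$cardiac_output))
  cat(sprintf("  central blood pools: arterial %.4g L, venous %.4g L\n",
              x$arterial_blood_volume, x$venous_blood_volume))
  print(x$organs, row.names = FALSE)
  invisible(x)
}

organ_row <- function(phys, organ) {
  i <- match(organ, phys$organs$name)
  if (is.na(i)) stop("unknown organ '", organ, "'", call. = FALSE)
  phys$organs[i, ]
}
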