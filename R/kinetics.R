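# MSC-specific kinetic parameters: partition coefficients and
# arrest/release/depletion rate constants.

#' Construct a cell kinetic parameter set
#'
#' Holds the cell-specific parameters of the PBK model: per organ a
#' partition coefficient `P` (unitless; venous outflow concentration is
#' `C_V / P`) and first-order arrest, release and depletion rate constants
#' (1/h), plus a depletion rate constant for the circulating blood pools.
#'
#' @param organs Data frame with columns `organ`, `partition`, `k_arrest`,
#'   `k_release`, `k_depletion`, one row per entry of [PBK_ORGANS].
#' @param blood_k_depletion Depletion rate constant (1/h) applied to the
#'   central arterial and venous blood pools.
#' @return Object of class `cell_kinetic_params`.
#' @export
cell_kinetic_params <- function(organs, blood_k_depletion) {
  organs <- as.data.frame(organs, stringsAsFactors = FALSE)
  needed <- c("organ", "partition", "k_arrest", "k_release", "k_depletion")
  if (!all(needed %in% names(organs))) {
    stop("organ table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(organs$organ, PBK_ORGANS) || anyDuplicated(organs$organ)) {
    stop("kinetic parameters must cover exactly the model organs", call. = FALSE)
  }
  organs <- organs[match(PBK_ORGANS, organs$organ), needed]
  rownames(organs) <- NULL
  if (any(!is.finite(organs$partition)) || any(organs$partition <= 0)) {
    stop("partition coefficients must be positive", call. = FALSE)
  }
  rates <- as.matrix(organs[, c("k_arrest", "k_release", "k_depletion")])
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rate constants must be non-negative", call. = FALSE)
  }
  if (!is.finite(blood_k_depletion) || blood_k_depletion < 0) {
    stop("blood_k_depletion must be non-negative", call. = FALSE)
  }
  structure(list(organs = organs,
                 blood_k_depletion = as.numeric(blood_k_depletion)),
            class = "cell_kinetic_params")
}

#' Load cell kinetic parameters
#'
#' `"table1"` loads the packaged fixture of MSC-specific parameters
#' estimated by curve fitting against the mouse biodistribution experiment
#' (lung arrest 5.434/h, blood depletion 0.636/h, spleen partition 1633.24,
#' ...). Any other value is treated as a path to a CSV in the same dialect
#' (columns organ, partition, k_arrest, k_release, k_depletion; a `blood`
#' row carrying only `k_depletion`).
#'
#' @param source `"table1"` or a CSV path.
#' @return A `cell_kinetic_params`.
#' @examples
#' p <- load_kinetic_params("table1")
#' p$organs
#' @export
load_kinetic_params <- function(source = "table1") {
  stopifnot(is.character(source), length(source) == 1L)
  if (source == "table1") {
    path <- system.file("extdata", "kinetics", "table1.csv",
                        package = "mscpbk", mustWork = TRUE)
  } else if (file.exists(source)) {
    path <- source
  } else {
    stop("unknown kinetic parameter source '", source, "'", call. = FALSE)
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  blood <- tab[tab$organ == "blood", , drop = FALSE]
  if (nrow(blood) != 1L || !is.finite(blood$k_depletion)) {
    stop("kinetic parameter file needs a 'blood' row with k_depletion",
         call. = FALSE)
  }
  cell_kinetic_params(organs = tab[tab$organ != "blood", ],
                      blood_k_depletion = blood$k_depletion)
}

#' Write cell kinetic parameters to CSV
#'
#' @param params A `cell_kinetic_params`.
#' @param path Output CSV path (same dialect as [load_kinetic_params()]).
#' @return `path`, invisibly.
#' @export
write_kinetic_params <- function(params, path) {
  stopifnot(inherits(params, "cell_kinetic_params"))
  blood <- data.frame(organ = "blood", partition = NA, k_arrest = NA,
                      k_release = NA, k_depletion = params$blood_k_depletion)
  utils::write.csv(rbind(blood, params$organs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Disease-specific variant of a parameter set
#'
#' Returns a copy of `base` with one organ's parameters rescaled, emulating
#' disease-altered cell--endothelium interaction (e.g. higher arrest and
#' lower depletion in an infarcted heart; higher partition and arrest in a
#' cirrhotic liver). All other organs and the blood depletion constant are
#' untouched.
#'
#' @param base A `cell_kinetic_params`.
#' @param organ Organ to modify (one of [PBK_ORGANS]).
#' @param arrest_multiplier,depletion_multiplier,partition_multiplier
#'   Positive multiplicative factors (default 1 = unchanged).
#' @return A new `cell_kinetic_params`.
#' @export
generate_disease_variant <- function(base, organ, arrest_multiplier = 1,
                                     depletion_multiplier = 1,
                                     partition_multiplier = 1) {
  stopifnot(inherits(base, "cell_kinetic_params"))
  if (!organ %in% PBK_ORGANS) stop("unknown organ '", organ, "'", call. = FALSE)
  m <- c(arrest_multiplier, depletion_multiplier, partition_multiplier)
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("multipliers must be positive", call. = FALSE)
  }
  org <- base$organs
  i <- match(organ, org$organ)
  org$k_arrest[i] <- org$k_arrest[i] * arrest_multiplier
  org$k_depletion[i] <- org$k_depletion[i] * depletion_multiplier
  org$partition[i] <- org$partition[i] * partition_multiplier
  cell_kinetic_params(org, base$blood_k_depletion)
}

#' @export
print.cell_kinetic_params <- function(x, ...) {
  cat("<cell_kinetic_params> blood k_depletion:", x$blood_k_depletion, "1/h\n")
  print(x$organs, row.names = FALSE)
  invisible(x)
}

# --- flat named-vector view used by calibration and sensitivity ---------

#' Flatten kinetic parameters to a named vector
#'
#' Names follow `"<organ>.<field>"` (e.g. `"lung.k_arrest"`) plus
#' `"blood.k_depletion"`; 25 entries in total. [vector_to_params()] inverts.
#'
#' @param params A `cell_kinetic_params`.
#' @return Named numeric vector.
#' @export
params_to_vector <- function(params) {
  stopifnot(inherits(params, "cell_kinetic_params"))
  org <- params$organs
  fields <- c("partition", "k_arrest", "k_release", "k_depletion")
  v <- unlist(lapply(seq_len(nrow(org)), function(i) {
    x <- as.numeric(org[i, fields])
    names(x) <- paste(org$organ[i], fields, sep = ".")
    x
  }))
  c(v, blood.k_depletion = params$blood_k_depletion)
}

#' Rebuild kinetic parameters from a named vector
#'
#' @param v Named vector as produced by [params_to_vector()].
#' @return A `cell_kinetic_params`.
#' @export
vector_to_params <- function(v) {
  fields <- c("partition", "k_arrest", "k_release", "k_depletion")
  org <- do.call(rbind, lapply(PBK_ORGANS, function(o) {
    keys <- paste(o, fields, sep = ".")
    if (!all(keys %in% names(v))) {
      stop("parameter vector is missing entries for organ '", o, "'",
           call. = FALSE)
    }
    out <- as.data.frame(as.list(v[keys]))
    names(out) <- fields
    cbind(organ = o, out)
  }))
  if (!"blood.k_depletion" %in% names(v)) {
    stop("parameter vector is missing 'blood.k_depletion'", call. = FALSE)
  }
  cell_kinetic_params(org, v[["blood.k_depletion"]])
}
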