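#' Base feature table
#'
#' The 42 base feature definitions underlying the 155-feature bank: numbered
#' abbreviations with their theoretical group. Features #1--#39 apply to the
#' continuous channels (EMG and, with exceptions, SCL); #40--#42 are
#' heart-rate-variability features computed from ECG only.
#'
#' @return A data.frame with columns `number`, `abbrev`, `group`.
#' @export
base_feature_table <- function() {
  tab <- data.frame(
    number = 1:42,
    abbrev = c(
      "HOMAV1", "HOMAV1n", "HOMAV2", "HOMAV2n", "MAV", "P2P", "PK", "RMS",
      "TMNP", "TMNV",
      "IQR", "R", "SD", "VAR",
      "IDS", "MD", "MIDS", "MMNDS", "SDMN", "SDSD",
      "ApEn", "FuzzyEn", "SampEn", "ShannonEn", "SpectralEn",
      "LDF", "PLDF",
      "CC", "MDCOH", "MI", "MICOH", "MNCOH", "MMNCOH",
      "BW", "CF", "MDF", "MNF", "MOF", "ZC",
      "MNRR", "RMSSD", "slopeRR"
    ),
    group = c(
      rep("Amplitude", 10),
      rep("Variability", 4),
      rep("Stationarity", 6),
      rep("Entropy", 5),
      rep("Linearity", 2),
      rep("Similarity", 6),
      rep("Frequency", 6),
      rep("Variability", 3)
    ),
    stringsAsFactors = FALSE
  )
  tab
}

# SCL carries 35 of the 39 continuous-channel features: the spectral-shape
# and zero-crossing features (BW, CF, MOF, ZC) are not defined for the slow
# electrodermal channel and are dropped.
.scl_excluded <- c("BW", "CF", "MOF", "ZC")

#' Feature registry
#'
#' The ordered list of all 155 instantiated feature names with their modality
#' and theoretical group. Names are modality-prefixed base abbreviations:
#' `z`/`c`/`t` for zygomaticus/corrugator/trapezius EMG (39 features each),
#' `s` for skin conductance (35 features), and `h` for ECG (3 HRV features),
#' e.g. `cP2P`, `sSDSD`, `hslopeRR`. The registry order is the canonical
#' column order of every feature matrix and the tie-break order used
#' throughout feature selection.
#'
#' @return A data.frame with columns `name`, `modality` (prefix letter),
#'   `channel` (`zEMG`, `cEMG`, `tEMG`, `SCL`, `ECG`), `abbrev` (base
#'   abbreviation), `number` (base feature number), `group`.
#' @examples
#' reg <- feature_registry()
#' nrow(reg)             # 155
#' table(reg$channel)
#' @export
feature_registry <- function() {
  if (!is.null(.pf_cache$registry)) return(.pf_cache$registry)
  tab <- base_feature_table()
  cont <- tab[tab$number <= 39, ]
  scl <- cont[!(cont$abbrev %in% .scl_excluded), ]
  hrv <- tab[tab$number >= 40, ]
  blocks <- list(
    data.frame(modality = "z", channel = "zEMG", cont, stringsAsFactors = FALSE),
    data.frame(modality = "c", channel = "cEMG", cont, stringsAsFactors = FALSE),
    data.frame(modality = "t", channel = "tEMG", cont, stringsAsFactors = FALSE),
    data.frame(modality = "s", channel = "SCL", scl, stringsAsFactors = FALSE),
    data.frame(modality = "h", channel = "ECG", hrv, stringsAsFactors = FALSE)
  )
  reg <- do.call(rbind, blocks)
  reg$name <- paste0(reg$modality, reg$abbrev)
  rownames(reg) <- NULL
  reg <- reg[, c("name", "modality", "channel", "abbrev", "number", "group")]
  .pf_cache$registry <- reg
  reg
}

.pf_cache <- new.env(parent = emptyenv())

#' Registry feature names
#'
#' @return Character vector of the 155 feature names in canonical order.
#' @export
feature_names <- function() feature_registry()$name

#' Dump the registry as JSON
#'
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_registry_json <- function(path) {
  jsonlite::write_json(feature_registry(), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
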