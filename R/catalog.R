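#' Baseline covariate catalog
#'
#' Returns the catalog of the 28 candidate baseline predictors used in the
#' SSc-ILD trial analysis: 8 binary clinical indicators and 20 continuous
#' laboratory / physiological measurements. Each entry carries the covariate
#' kind (how it is validated and which tests are applied to it) and its
#' measurement unit as metadata; no unit conversion is ever attempted.
#'
#' @return A data frame with one row per covariate and columns `name`,
#'   `kind` (`"binary"` or `"continuous"`), `unit` and `description`.
#' @examples
#' cat28 <- covariate_catalog()
#' table(cat28$kind)
#' @export
covariate_catalog <- function() {
  spec <- function(name, kind, unit, description) {
    data.frame(name = name, kind = kind, unit = unit,
               description = description, stringsAsFactors = FALSE)
  }
  out <- rbind(
    spec("sex",                  "binary", "", "female sex"),
    spec("prev_immunosuppressants", "binary", "",
         "previous use of immunosuppressants and/or biologics"),
    spec("diffuse_cutaneous",    "binary", "", "diffuse cutaneous SSc subtype"),
    spec("puffy_fingers",        "binary", "", "puffy fingers"),
    spec("skin_ulcer",           "binary", "", "skin ulcer"),
    spec("reflux_esophagitis",   "binary", "", "reflux esophagitis"),
    spec("barrett_esophagus",    "binary", "", "Barrett's esophagus"),
    spec("arthritis",            "binary", "", "arthritis"),
    spec("age",                  "continuous", "years", "age at baseline"),
    spec("disease_duration",     "continuous", "months",
         "months since first non-Raynaud symptom"),
    spec("MRSS",                 "continuous", "score",
         "modified Rodnan skin score"),
    spec("ATA_titre",            "continuous", "U/ml",
         "anti-topoisomerase I antibody titre"),
    spec("ACA_titre",            "continuous", "U/ml",
         "anti-centromere antibody titre"),
    spec("ARA_titre",            "continuous", "U/ml",
         "anti-RNA polymerase III antibody titre"),
    spec("CD19",                 "continuous", "cells/ul",
         "CD19-positive cells in peripheral blood"),
    spec("CD20",                 "continuous", "cells/ul",
         "CD20-positive cells in peripheral blood"),
    spec("ppFVC",                "continuous", "%",
         "percent-predicted forced vital capacity"),
    spec("DLco",                 "continuous", "%",
         "percent-predicted diffusing capacity for carbon monoxide"),
    spec("KL6",                  "continuous", "U/ml",
         "serum Krebs von den Lungen-6"),
    spec("SPA",                  "continuous", "ng/ml", "serum surfactant protein A"),
    spec("SPD",                  "continuous", "ng/ml", "serum surfactant protein D"),
    spec("total_protein",        "continuous", "g/dl", "total serum protein"),
    spec("CRP",                  "continuous", "mg/dl", "serum C-reactive protein"),
    spec("IgG",                  "continuous", "mg/dl", "serum IgG"),
    spec("IgM",                  "continuous", "mg/dl", "serum IgM"),
    spec("BNP",                  "continuous", "pg/ml",
         "serum brain natriuretic peptide"),
    spec("haemoglobin",          "continuous", "g/dl", "haemoglobin"),
    spec("interstitial_shadow",  "continuous", "% of lung",
         "area occupied by interstitial shadows on HRCT")
  )
  rownames(out) <- NULL
  out
}

validate_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog),
            all(c("name", "kind", "unit") %in% names(catalog)))
  if (anyDuplicated(catalog$name))
    stop("duplicate covariate names in catalog: ",
         paste(unique(catalog$name[duplicated(catalog$name)]), collapse = ", "))
  bad <- setdiff(unique(catalog$kind), c("binary", "continuous"))
  if (length(bad)) stop("unknown covariate kind: ", paste(bad, collapse = ", "))
  invisible(catalog)
}
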