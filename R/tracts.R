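#' White-matter tract catalog
#'
#' Returns the catalog of 54 white-matter tracts used throughout the package:
#' 25 bilateral pairs (50 unilateral tracts) plus 4 corpus callosum tracts,
#' each labelled with its tract system.
#'
#' @details Systems follow the standard functional grouping of the HCP
#'   population tractography atlas: dorsal association (AF, FAT, PAT,
#'   SLF1-3), ventral association (IFOF, ILF, UF, MdLF), limbic (cingulum
#'   subdivisions, fornix), sensorimotor (CST, OR, VOF), thalamic radiations,
#'   corticostriatal tracts, and callosal tracts.
#'
#' @return A data.frame with columns `tract` (base tract id), `hemisphere`
#'   (`"L"`, `"R"` or `"M"` for midline callosal tracts), `system`, and
#'   `pair_id` (shared by the two hemispheres of a bilateral pair).
#' @export
#' @examples
#' tc <- tract_catalog()
#' nrow(tc)            # 54 unilateral tracts
#' table(tc$system)
tract_catalog <- function() {
  systems <- list(
    `dorsal-association`  = c("AF", "FAT", "PAT", "SLF1", "SLF2", "SLF3"),
    `ventral-association` = c("IFOF", "ILF", "UF", "MdLF"),
    limbic                = c("C_FPH", "C_FP", "C_PH", "C_PHP", "C_PO", "F"),
    sensorimotor          = c("CST", "OR", "VOF"),
    thalamic              = c("TR_A", "TR_P", "TR_S"),
    corticostriatal       = c("CS_A", "CS_P", "CS_S")
  )
  rows <- do.call(rbind, lapply(names(systems), function(sys) {
    do.call(rbind, lapply(systems[[sys]], function(tr) {
      data.frame(tract = tr, hemisphere = c("L", "R"), system = sys,
                 pair_id = tr, stringsAsFactors = FALSE)
    }))
  }))
  cc <- data.frame(tract = c("CC_Body", "CC_Major", "CC_Minor", "CC_Tap"),
                   hemisphere = "M", system = "callosal",
                   pair_id = c("CC_Body", "CC_Major", "CC_Minor", "CC_Tap"),
                   stringsAsFactors = FALSE)
  out <- rbind(rows, cc)
  rownames(out) <- NULL
  out
}

#' Unique tract model ids (bilateral pairs and callosal tracts)
#'
#' The 29 tract-specific model units: 25 bilateral pairs (left+right
#' concatenated) and 4 callosal tracts.
#'
#' @param catalog a tract catalog as returned by [tract_catalog()].
#' @return Character vector of pair ids in catalog order.
#' @export
tract_pairs <- function(catalog = tract_catalog()) {
  unique(catalog$pair_id)
}
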