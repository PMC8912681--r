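#' DXA fat-free mass
#'
#' Fat-free mass from a whole-body DXA scan is the total-body lean soft
#' tissue plus bone mineral content.  BMC is reported by the densitometer in
#' grams and converted to kg here; the conversion is explicit, never implied.
#'
#' @param lean_soft_tissue_kg Total-body lean soft tissue mass in kg.
#' @param bmc_g Bone mineral content in g.
#' @return Fat-free mass in kg.
#' @examples
#' dxa_ffm(31.8, 1900)  # 33.7
#' @export
dxa_ffm <- function(lean_soft_tissue_kg, bmc_g) {
  stop_unless(all(lean_soft_tissue_kg >= 0, na.rm = TRUE),
              "lean_soft_tissue_kg must be non-negative")
  stop_unless(all(bmc_g >= 0, na.rm = TRUE), "bmc_g must be non-negative")
  lean_soft_tissue_kg + bmc_g / 1000
}
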