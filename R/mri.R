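#' Total fat mass from an MRI fat-voxel count
#'
#' Whole-body MRI segmentation yields a count of voxels classified as
#' adipose tissue; fat mass is the count times the voxel volume times the
#' adipose-tissue density (default 0.92 kg/L, configurable).
#'
#' @param n_fat_voxels Number of fat voxels, non-negative integer.
#' @param voxel_volume_L Volume of one voxel in L, positive.
#' @param adipose_density_kg_per_L Adipose tissue density in kg/L, within
#'   (0.8, 1.1).
#' @return Fat mass in kg.
#' @examples
#' mri_fat_mass(1000, 0.01, 0.92)  # 9.2 kg
#' @export
mri_fat_mass <- function(n_fat_voxels, voxel_volume_L,
                         adipose_density_kg_per_L = 0.92) {
  stop_unless(all(n_fat_voxels >= 0, na.rm = TRUE),
              "n_fat_voxels must be non-negative")
  stop_unless(all(voxel_volume_L > 0, na.rm = TRUE),
              "voxel_volume_L must be positive")
  stop_unless(all(adipose_density_kg_per_L > 0.8 &
                    adipose_density_kg_per_L < 1.1),
              "adipose density must lie in (0.8, 1.1) kg/L")
  n_fat_voxels * voxel_volume_L * adipose_density_kg_per_L
}
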