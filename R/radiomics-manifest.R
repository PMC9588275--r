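# The default 103-feature manifest: 13 shape, 17 first-order and 73
# texture features (22 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM + 5 NGTDM),
# named in the conventional radiomics style (class_FeatureName).

manifest_names <- list(
  shape = c("MeshVolume", "SurfaceArea", "SurfaceVolumeRatio", "Sphericity",
            "Maximum3DDiameter", "Maximum2DDiameterSlice",
            "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
            "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
            "Elongation", "Flatness"),
  firstorder = c("Energy", "Entropy", "Minimum", "Percentile10",
                 "Percentile90", "Maximum", "Mean", "Median",
                 "InterquartileRange", "Range", "MeanAbsoluteDeviation",
                 "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                 "Skewness", "Kurtosis", "Variance", "Uniformity"),
  glcm = c("Autocorrelation", "ClusterProminence", "ClusterShade",
           "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
           "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
           "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
           "JointEnergy", "JointEntropy", "MaximumProbability", "SumEntropy",
           "SumSquares"),
  glrlm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "GrayLevelVariance", "HighGrayLevelRunEmphasis",
            "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
            "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
            "RunEntropy", "RunLengthNonUniformity",
            "RunLengthNonUniformityNormalized", "RunPercentage",
            "RunVariance", "ShortRunEmphasis",
            "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis"),
  glszm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
            "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
            "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
            "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
            "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
            "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy", "ZonePercentage",
            "ZoneVariance"),
  gldm = c("DependenceEntropy", "DependenceNonUniformity",
           "DependenceNonUniformityNormalized", "DependenceVariance",
           "GrayLevelNonUniformity", "GrayLevelVariance",
           "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
           "LargeDependenceHighGrayLevelEmphasis",
           "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
           "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
           "SmallDependenceLowGrayLevelEmphasis"),
  ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
)

texture_classes <- c("glcm", "glrlm", "glszm", "gldm", "ngtdm")

# GLCM subset the builtin backend computes at formula level
builtin_glcm_features <- c("Autocorrelation", "ClusterProminence",
                           "ClusterShade", "Contrast", "Correlation",
                           "DifferenceEntropy", "Id", "Idm", "JointEnergy",
                           "JointEntropy", "MaximumProbability", "SumEntropy")

#' Radiomic feature manifest
#'
#' Returns the ordered default manifest of the 103 features the extraction
#' pipeline accounts for: 13 morphology (shape), 17 intensity-histogram
#' (first-order) and 73 texture features. Shape features are computed from
#' the mask alone and are unaffected by denoising, so
#' `exclude_shape = TRUE` returns the 90-feature subset used for
#' reproducibility analysis.
#'
#' @param classes feature classes to include (default: all).
#' @param exclude_shape drop the shape class (reproducibility subset).
#' @return A data frame with columns `class` and `name` (`class_name` keys
#'   in `feature`), with attribute `class_counts`.
#' @export
feature_manifest <- function(classes = names(manifest_names),
                             exclude_shape = FALSE) {
  unknown <- setdiff(classes, names(manifest_names))
  if (length(unknown) > 0L) {
    stopf("unknown feature class(es): %s", paste(unknown, collapse = ", "))
  }
  if (exclude_shape) classes <- setdiff(classes, "shape")
  out <- do.call(rbind, lapply(classes, function(cl) {
    data.frame(class = cl, name = manifest_names[[cl]],
               feature = paste(cl, manifest_names[[cl]], sep = "_"))
  }))
  rownames(out) <- NULL
  attr(out, "class_counts") <- vapply(classes, function(cl) {
    length(manifest_names[[cl]])
  }, integer(1))
  out
}
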