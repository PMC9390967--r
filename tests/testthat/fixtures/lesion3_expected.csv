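feature,value
original_firstorder_10Percentile,234.668263
original_firstorder_90Percentile,245.665112
original_firstorder_Energy,33207316.978
original_firstorder_Entropy,-0
original_firstorder_InterquartileRange,5.6152375
original_firstorder_Kurtosis,2.41015635539
original_firstorder_Maximum,249.00663
original_firstorder_Mean,240.913409371
original_firstorder_MeanAbsoluteDeviation,3.23091300308
original_firstorder_Median,241.49661
original_firstorder_Minimum,231.59268
original_firstorder_Range,17.41395
original_firstorder_RobustMeanAbsoluteDeviation,2.32603384811
original_firstorder_RootMeanSquared,240.945533185
original_firstorder_Skewness,-0.385908397519
original_firstorder_TotalEnergy,37358231.6003
original_firstorder_Uniformity,1
original_firstorder_Variance,15.4791470272
original_glcm_Autocorrelation,1
original_glcm_ClusterProminence,0
original_glcm_ClusterShade,0
original_glcm_ClusterTendency,0
original_glcm_Contrast,0
original_glcm_Correlation,1
original_glcm_DifferenceAverage,0
original_glcm_DifferenceEntropy,0
original_glcm_DifferenceVariance,0
original_glcm_Id,1
original_glcm_Idm,1
original_glcm_Idmn,1
original_glcm_Idn,1
original_glcm_Imc1,0
original_glcm_Imc2,0
original_glcm_InverseVariance,0
original_glcm_JointAverage,1
original_glcm_JointEnergy,1
original_glcm_JointEntropy,0
original_glcm_MCC,1
original_glcm_MaximumProbability,1
original_glcm_SumAverage,2
original_glcm_SumEntropy,0
original_glcm_SumSquares,0
original_gldm_DependenceEntropy,2.88366617591
original_gldm_DependenceNonUniformity,135.188811189
original_gldm_DependenceNonUniformityNormalized,0.236344075505
original_gldm_DependenceVariance,23.0189251308
original_gldm_GrayLevelNonUniformity,572
original_gldm_GrayLevelVariance,0
original_gldm_HighGrayLevelEmphasis,1
original_gldm_LargeDependenceEmphasis,376.090909091
original_gldm_LargeDependenceHighGrayLevelEmphasis,376.090909091
original_gldm_LargeDependenceLowGrayLevelEmphasis,376.090909091
original_gldm_LowGrayLevelEmphasis,1
original_gldm_SmallDependenceEmphasis,0.00349106708602
original_gldm_SmallDependenceHighGrayLevelEmphasis,0.00349106708602
original_gldm_SmallDependenceLowGrayLevelEmphasis,0.00349106708602
original_glrlm_GrayLevelNonUniformity,180.615384615
original_glrlm_GrayLevelNonUniformityNormalized,1
original_glrlm_GrayLevelVariance,0
original_glrlm_HighGrayLevelRunEmphasis,1
original_glrlm_LongRunEmphasis,43.7288993946
original_glrlm_LongRunHighGrayLevelEmphasis,43.7288993946
original_glrlm_LongRunLowGrayLevelEmphasis,43.7288993946
original_glrlm_LowGrayLevelRunEmphasis,1
original_glrlm_RunEntropy,1.74942759908
original_glrlm_RunLengthNonUniformity,73.8363360332
original_glrlm_RunLengthNonUniformityNormalized,0.360027851026
original_glrlm_RunPercentage,0.315761161915
original_glrlm_RunVariance,4.16067038365
original_glrlm_ShortRunEmphasis,0.19478303554
original_glrlm_ShortRunHighGrayLevelEmphasis,0.19478303554
original_glrlm_ShortRunLowGrayLevelEmphasis,0.19478303554
original_glszm_GrayLevelNonUniformity,1
original_glszm_GrayLevelNonUniformityNormalized,1
original_glszm_GrayLevelVariance,0
original_glszm_HighGrayLevelZoneEmphasis,1
original_glszm_LargeAreaEmphasis,327184
original_glszm_LargeAreaHighGrayLevelEmphasis,327184
original_glszm_LargeAreaLowGrayLevelEmphasis,327184
original_glszm_LowGrayLevelZoneEmphasis,1
original_glszm_SizeZoneNonUniformity,1
original_glszm_SizeZoneNonUniformityNormalized,1
original_glszm_SmallAreaEmphasis,3.05638417527e-06
original_glszm_SmallAreaHighGrayLevelEmphasis,3.05638417527e-06
original_glszm_SmallAreaLowGrayLevelEmphasis,3.05638417527e-06
original_glszm_ZoneEntropy,-0
original_glszm_ZonePercentage,0.00174825174825
original_glszm_ZoneVariance,0
original_ngtdm_Busyness,0
original_ngtdm_Coarseness,1000000
original_ngtdm_Complexity,0
original_ngtdm_Contrast,0
original_ngtdm_Strength,0
original_shape_Elongation,0.627464116915
original_shape_Flatness,0.414119166352
original_shape_LeastAxisLength,6.22656506827
original_shape_MajorAxisLength,15.0356843493
original_shape_Maximum2DDiameterColumn,14.3896664312
original_shape_Maximum2DDiameterRow,9.9530146187
original_shape_Maximum2DDiameterSlice,14.7351620283
original_shape_Maximum3DDiameter,14.870272358
original_shape_MeshVolume,634.3125
original_shape_MinorAxisLength,9.43435240247
original_shape_Sphericity,0.743092306076
original_shape_SurfaceArea,480.444846982
original_shape_SurfaceVolumeRatio,0.757426106189
original_shape_VoxelVolume,643.5
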