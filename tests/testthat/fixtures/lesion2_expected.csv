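feature,value
original_firstorder_10Percentile,231.362485
original_firstorder_90Percentile,241.8357
original_firstorder_Energy,33820290.9541
original_firstorder_Entropy,0.0911547461968
original_firstorder_InterquartileRange,5.5687525
original_firstorder_Kurtosis,3.41597024438
original_firstorder_Maximum,247.08866
original_firstorder_Mean,236.589085033
original_firstorder_MeanAbsoluteDeviation,3.44356994891
original_firstorder_Median,236.858195
original_firstorder_Minimum,221.09243
original_firstorder_Range,25.99623
original_firstorder_RobustMeanAbsoluteDeviation,2.34223805427
original_firstorder_RootMeanSquared,236.630216151
original_firstorder_Skewness,-0.389130414824
original_firstorder_TotalEnergy,19023913.6617
original_firstorder_Uniformity,0.977089820622
original_firstorder_Variance,19.4640387513
original_glcm_Autocorrelation,1.02169962985
original_glcm_ClusterProminence,0.0285924912189
original_glcm_ClusterShade,0.0237439241183
original_glcm_ClusterTendency,0.0219453629503
original_glcm_Contrast,0.0196096816957
original_glcm_Correlation,0.0450351808281
original_glcm_DifferenceAverage,0.0196096816957
original_glcm_DifferenceEntropy,0.138995233529
original_glcm_DifferenceVariance,0.0192184217052
original_glcm_Id,0.990195159152
original_glcm_Idm,0.990195159152
original_glcm_Idmn,0.996078063661
original_glcm_Idn,0.993463439435
original_glcm_Imc1,-0.0267284015482
original_glcm_Imc2,0.0436849290456
original_glcm_InverseVariance,0.0196096816957
original_glcm_JointAverage,1.01050149023
original_glcm_JointEnergy,0.960004055972
original_glcm_JointEntropy,0.165277917738
original_glcm_MCC,0.0603109766059
original_glcm_MaximumProbability,0.97969366892
original_glcm_SumAverage,2.02100298046
original_glcm_SumEntropy,0.145668236042
original_glcm_SumSquares,0.0103887611615
original_gldm_DependenceEntropy,3.05280086301
original_gldm_DependenceNonUniformity,126.11589404
original_gldm_DependenceNonUniformityNormalized,0.208801149072
original_gldm_DependenceVariance,26.2477413271
original_gldm_GrayLevelNonUniformity,590.162251656
original_gldm_GrayLevelVariance,0.011455089689
original_gldm_HighGrayLevelEmphasis,1.03476821192
original_gldm_LargeDependenceEmphasis,383.357615894
original_gldm_LargeDependenceHighGrayLevelEmphasis,383.571192053
original_gldm_LargeDependenceLowGrayLevelEmphasis,383.304221854
original_gldm_LowGrayLevelEmphasis,0.99130794702
original_gldm_SmallDependenceEmphasis,0.0055216713351
original_gldm_SmallDependenceHighGrayLevelEmphasis,0.0121441878914
original_gldm_SmallDependenceLowGrayLevelEmphasis,0.00386604219602
original_glrlm_GrayLevelNonUniformity,175.581390421
original_glrlm_GrayLevelNonUniformityNormalized,0.913902190803
original_glrlm_GrayLevelVariance,0.0430489045985
original_glrlm_HighGrayLevelRunEmphasis,1.13744855435
original_glrlm_LongRunEmphasis,36.0411014579
original_glrlm_LongRunHighGrayLevelEmphasis,36.2359397744
original_glrlm_LongRunLowGrayLevelEmphasis,35.9923918788
original_glrlm_LowGrayLevelRunEmphasis,0.965637861414
original_glrlm_RunEntropy,1.93778619114
original_glrlm_RunLengthNonUniformity,84.930607479
original_glrlm_RunLengthNonUniformityNormalized,0.382717378698
original_glrlm_RunPercentage,0.311640346409
original_glrlm_RunVariance,6.15040808683
original_glrlm_ShortRunEmphasis,0.216150609631
original_glrlm_ShortRunHighGrayLevelEmphasis,0.339251723442
original_glrlm_ShortRunLowGrayLevelEmphasis,0.185375331178
original_glszm_GrayLevelNonUniformity,2.5
original_glszm_GrayLevelNonUniformityNormalized,0.625
original_glszm_GrayLevelVariance,0.1875
original_glszm_HighGrayLevelZoneEmphasis,3.25
original_glszm_LargeAreaEmphasis,89106.5
original_glszm_LargeAreaHighGrayLevelEmphasis,89119.25
original_glszm_LargeAreaLowGrayLevelEmphasis,89103.3125
original_glszm_LowGrayLevelZoneEmphasis,0.4375
original_glszm_SizeZoneNonUniformity,1.5
original_glszm_SizeZoneNonUniformityNormalized,0.375
original_glszm_SmallAreaEmphasis,0.152778479219
original_glszm_SmallAreaHighGrayLevelEmphasis,0.611111812552
original_glszm_SmallAreaLowGrayLevelEmphasis,0.0381951458858
original_glszm_ZoneEntropy,1.5
original_glszm_ZonePercentage,0.00662251655629
original_glszm_ZoneVariance,66305.5
original_ngtdm_Busyness,2.75014863315
original_ngtdm_Coarseness,0.188357198353
original_ngtdm_Complexity,0.0175796747196
original_ngtdm_Contrast,0.000222044718048
original_ngtdm_Strength,0.170824872094
original_shape_Elongation,1
original_shape_Flatness,0.269356976772
original_shape_LeastAxisLength,3.23881004434
original_shape_MajorAxisLength,12.0242292706
original_shape_Maximum2DDiameterColumn,11.426394882
original_shape_Maximum2DDiameterRow,11.426394882
original_shape_Maximum2DDiameterSlice,11.8585412256
original_shape_Maximum3DDiameter,11.9006302354
original_shape_MeshVolume,335.34375
original_shape_MinorAxisLength,12.0242292706
original_shape_Sphericity,0.669108847835
original_shape_SurfaceArea,348.857043677
original_shape_SurfaceVolumeRatio,1.04029684071
original_shape_VoxelVolume,339.75
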