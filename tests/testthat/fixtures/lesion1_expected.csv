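feature,value
original_firstorder_10Percentile,226.126353
original_firstorder_90Percentile,239.777388
original_firstorder_Energy,36896215.4261
original_firstorder_Entropy,0.0289704773047
original_firstorder_InterquartileRange,6.3075275
original_firstorder_Kurtosis,2.79434256365
original_firstorder_Maximum,245.33717
original_firstorder_Mean,232.881773515
original_firstorder_MeanAbsoluteDeviation,3.94233881522
original_firstorder_Median,232.75654
original_firstorder_Minimum,219.70132
original_firstorder_Range,25.63585
original_firstorder_RobustMeanAbsoluteDeviation,2.68077426984
original_firstorder_RootMeanSquared,232.935914647
original_firstorder_Skewness,-0.0674023913323
original_firstorder_TotalEnergy,20754121.1772
original_firstorder_Uniformity,0.994134948097
original_firstorder_Variance,25.2198971276
original_glcm_Autocorrelation,1.00543249208
original_glcm_ClusterProminence,0.00689685240235
original_glcm_ClusterShade,0.00595605990076
original_glcm_ClusterTendency,0.00552655817901
original_glcm_Contrast,0.0050638511359
original_glcm_Correlation,0.0359227831325
original_glcm_DifferenceAverage,0.0050638511359
original_glcm_DifferenceEntropy,0.0457845268712
original_glcm_DifferenceVariance,0.00503739245391
original_glcm_Id,0.997468074432
original_glcm_Idm,0.997468074432
original_glcm_Idmn,0.998987229773
original_glcm_Idn,0.998312049621
original_glcm_Imc1,-0.0269654398315
original_glcm_Imc2,0.0153199406317
original_glcm_InverseVariance,0.0050638511359
original_glcm_JointAverage,1.00265480588
original_glcm_JointEnergy,0.989667402889
original_glcm_JointEntropy,0.0521665078469
original_glcm_MCC,0.0407537454671
original_glcm_MaximumProbability,0.99481326855
original_glcm_SumAverage,2.00530961177
original_glcm_SumEntropy,0.047102656711
original_glcm_SumSquares,0.00264760232873
original_gldm_DependenceEntropy,2.68336642557
original_gldm_DependenceNonUniformity,186.988235294
original_gldm_DependenceNonUniformityNormalized,0.274982698962
original_gldm_DependenceVariance,25.1858131488
original_gldm_GrayLevelNonUniformity,676.011764706
original_gldm_GrayLevelVariance,0.00293252595156
original_gldm_HighGrayLevelEmphasis,1.00882352941
original_gldm_LargeDependenceEmphasis,395.182352941
original_gldm_LargeDependenceHighGrayLevelEmphasis,395.217647059
original_gldm_LargeDependenceLowGrayLevelEmphasis,395.173529412
original_gldm_LowGrayLevelEmphasis,0.997794117647
original_gldm_SmallDependenceEmphasis,0.00404331527525
original_gldm_SmallDependenceHighGrayLevelEmphasis,0.00624919762819
original_gldm_SmallDependenceLowGrayLevelEmphasis,0.00349184468702
original_glrlm_GrayLevelNonUniformity,199.282351301
original_glrlm_GrayLevelNonUniformityNormalized,0.973399536402
original_glrlm_GrayLevelVariance,0.013300231799
original_glrlm_HighGrayLevelRunEmphasis,1.04074699245
original_glrlm_LongRunEmphasis,46.4955981974
original_glrlm_LongRunHighGrayLevelEmphasis,46.5487078272
original_glrlm_LongRunLowGrayLevelEmphasis,46.4823207899
original_glrlm_LowGrayLevelRunEmphasis,0.989813251888
original_glrlm_RunEntropy,1.71278852434
original_glrlm_RunLengthNonUniformity,103.507536004
original_glrlm_RunLengthNonUniformityNormalized,0.43415716296
original_glrlm_RunPercentage,0.298642533937
original_glrlm_RunVariance,5.37827998472
original_glrlm_ShortRunEmphasis,0.190063537657
original_glrlm_ShortRunHighGrayLevelEmphasis,0.227719870763
original_glrlm_ShortRunLowGrayLevelEmphasis,0.18064945438
original_glszm_GrayLevelNonUniformity,1
original_glszm_GrayLevelNonUniformityNormalized,0.5
original_glszm_GrayLevelVariance,0.25
original_glszm_HighGrayLevelZoneEmphasis,2.5
original_glszm_LargeAreaEmphasis,229844
original_glszm_LargeAreaHighGrayLevelEmphasis,229850
original_glszm_LargeAreaLowGrayLevelEmphasis,229842.5
original_glszm_LowGrayLevelZoneEmphasis,0.625
original_glszm_SizeZoneNonUniformity,1
original_glszm_SizeZoneNonUniformityNormalized,0.5
original_glszm_SmallAreaEmphasis,0.125001087704
original_glszm_SmallAreaHighGrayLevelEmphasis,0.500001087704
original_glszm_SmallAreaLowGrayLevelEmphasis,0.0312510877037
original_glszm_ZoneEntropy,1
original_glszm_ZonePercentage,0.00294117647059
original_glszm_ZoneVariance,114244
original_ngtdm_Busyness,0.955458251093
original_ngtdm_Coarseness,0.527967640657
original_ngtdm_Complexity,0.00557075139478
original_ngtdm_Contrast,1.62860542865e-05
original_ngtdm_Strength,0.529598893407
original_shape_Elongation,0.872999613693
original_shape_Flatness,0.237921352901
original_shape_LeastAxisLength,3.24774227019
original_shape_MajorAxisLength,13.6504867284
original_shape_Maximum2DDiameterColumn,12.9059094991
original_shape_Maximum2DDiameterRow,11.426394882
original_shape_Maximum2DDiameterSlice,13.29003386
original_shape_Maximum3DDiameter,13.3276029353
original_shape_MeshVolume,377.8125
original_shape_MinorAxisLength,11.9168696407
original_shape_Sphericity,0.656261435579
original_shape_SurfaceArea,385.115905243
original_shape_SurfaceVolumeRatio,1.01933076656
original_shape_VoxelVolume,382.5
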