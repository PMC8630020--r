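# Properties of the eight reference sediment cores.
# water_depth_m in m; sedimentation_rate_m_yr in m/yr; organic matter
# content in % dry weight (range as published; NA where unavailable).
region,core,coring_method,latitude,longitude,water_depth_m,om_content_pct,sedimentation_rate_m_yr
Arabian Sea,SAST,Multiple-coring,10.03,65.00,4424,0.05-0.4,1.2e-5
Arctic Mid-Ocean Ridge,GC04,Gravity coring,72.27,1.70,2668,0.3-1.0,2.0e-5
Arctic Mid-Ocean Ridge,GC05,Gravity coring,76.92,7.12,3007,0.3-1.8,2.5e-5
Arctic Mid-Ocean Ridge,GC08,Gravity coring,71.97,0.17,2476,0.3-0.6,2.0e-5
Arctic Mid-Ocean Ridge,GC09,Gravity coring,73.70,7.57,1653,0.2-0.5,5.0e-5
North Pond,NP_U1383E,Piston coring,22.80,-46.05,4476,<0.3,9.4e-6
North Pacific Gyre,NPG_11,Multiple/gravity/piston coring,30.35,-15.75,6000,NA,1.0e-6
South Pacific Gyre,SPG_U1370,Piston coring,-41.85,-153.10,5075,0-0.25,1.5e-6
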