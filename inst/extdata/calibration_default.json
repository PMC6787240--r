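{
  "description": "Reference phantom calibrations for recurrent glioma (REC) vs post-treatment related effects (PTRE), from published FET-PET/ADC group summaries. Means are printed group means; SDs are pooled between-patient SDs implied by the printed MD +/- SE at n = 32/10 (ADC: 91; TBR: 0.45), via calibrate_from_summary. tbr80_ratio is the printed TBR80mean/TBRmax group ratio.",
  "groups": [
    {
      "group": "REC",
      "tbrmax_mean": 3.18,
      "tbrmax_sd": 1.2421177,
      "core_adc_mean_mean": 1313,
      "core_adc_mean_sd": 251.18381,
      "bg_suv_mean": 0.94,
      "bg_adc_mean": 768,
      "tbr_truncation_floor": 1.4,
      "tbr80_ratio": 0.8647799
    },
    {
      "group": "PTRE",
      "tbrmax_mean": 2.09,
      "tbrmax_sd": 1.2421177,
      "core_adc_mean_mean": 1029,
      "core_adc_mean_sd": 251.18381,
      "bg_suv_mean": 1.11,
      "bg_adc_mean": 755,
      "tbr_truncation_floor": 1.4,
      "tbr80_ratio": 0.8612440
    }
  ]
}
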