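{
  "description": "Registry of the CSF proteomic cohorts used for discovery, model training, diagnostic validation and differential diagnosis. Counts are per-study; printed role totals are kept separately under 'totals' for cross-checking. NA means not reported.",
  "studies": [
    {"study": "Bader (Sweden)", "role": "discovery", "country": "Sweden",
     "n_total": 60, "aneg_tneg": 31, "apos_tpos": 29,
     "aneg_tneg_cu": null, "apos_tpos_ci": null, "apos_tpos_mci": null,
     "apos_tpos_dem": null, "n_female": 24, "n_male": 36,
     "platform": "mass_spec"},
    {"study": "Bader (Magdeburg)", "role": "discovery", "country": "Germany",
     "n_total": 38, "aneg_tneg": 12, "apos_tpos": 26,
     "aneg_tneg_cu": 13, "apos_tpos_ci": 25, "apos_tpos_mci": null,
     "apos_tpos_dem": null, "n_female": 24, "n_male": 14,
     "platform": "mass_spec"},
    {"study": "Bai", "role": "discovery", "country": "USA",
     "n_total": 13, "aneg_tneg": 5, "apos_tpos": 8,
     "aneg_tneg_cu": 5, "apos_tpos_ci": 6, "apos_tpos_mci": 1,
     "apos_tpos_dem": 5, "n_female": 7, "n_male": 6,
     "platform": "mass_spec"},
    {"study": "Higginbotham (Discovery)", "role": "discovery",
     "country": "USA", "n_total": 40, "aneg_tneg": 20, "apos_tpos": 20,
     "aneg_tneg_cu": 20, "apos_tpos_ci": 20, "apos_tpos_mci": null,
     "apos_tpos_dem": null, "n_female": 17, "n_male": 23,
     "platform": "mass_spec"},
    {"study": "Higginbotham (Replication 4)", "role": "discovery",
     "country": "USA", "n_total": 35, "aneg_tneg": 18, "apos_tpos": 17,
     "aneg_tneg_cu": 17, "apos_tpos_ci": 18, "apos_tpos_mci": null,
     "apos_tpos_dem": null, "n_female": 14, "n_male": 21,
     "platform": "mass_spec"},
    {"study": "Liu", "role": "discovery", "country": "China",
     "n_total": 60, "aneg_tneg": 30, "apos_tpos": 30,
     "aneg_tneg_cu": 30, "apos_tpos_ci": 30, "apos_tpos_mci": 30,
     "apos_tpos_dem": 0, "n_female": 27, "n_male": 33,
     "platform": "mass_spec"},
    {"study": "Sathe", "role": "discovery", "country": "USA",
     "n_total": 10, "aneg_tneg": 5, "apos_tpos": 5,
     "aneg_tneg_cu": 5, "apos_tpos_ci": 5, "apos_tpos_mci": 5,
     "apos_tpos_dem": 0, "n_female": null, "n_male": null,
     "platform": "mass_spec"},
    {"study": "Tao", "role": "discovery", "country": "China",
     "n_total": 58, "aneg_tneg": 20, "apos_tpos": 38,
     "aneg_tneg_cu": 20, "apos_tpos_ci": 38, "apos_tpos_mci": 7,
     "apos_tpos_dem": 31, "n_female": 30, "n_male": 28,
     "platform": "mass_spec"},
    {"study": "van der Ende", "role": "discovery",
     "country": "Netherlands, USA", "n_total": 425, "aneg_tneg": 195,
     "apos_tpos": 230, "aneg_tneg_cu": null, "apos_tpos_ci": null,
     "apos_tpos_mci": null, "apos_tpos_dem": null, "n_female": 174,
     "n_male": 251, "platform": "pea"},
    {"study": "Wang", "role": "discovery", "country": "USA",
     "n_total": 20, "aneg_tneg": 9, "apos_tpos": 11,
     "aneg_tneg_cu": 9, "apos_tpos_ci": 11, "apos_tpos_mci": null,
     "apos_tpos_dem": null, "n_female": null, "n_male": null,
     "platform": "mass_spec"},
    {"study": "Bader (Sweden)", "role": "training", "country": "Sweden",
     "n_total": 60, "aneg_tneg": 31, "apos_tpos": 29,
     "aneg_tneg_cu": null, "apos_tpos_ci": null, "apos_tpos_mci": null,
     "apos_tpos_dem": null, "n_female": 24, "n_male": 36,
     "platform": "mass_spec"},
    {"study": "Tao", "role": "training", "country": "China",
     "n_total": 58, "aneg_tneg": 20, "apos_tpos": 38,
     "aneg_tneg_cu": 20, "apos_tpos_ci": 38, "apos_tpos_mci": 7,
     "apos_tpos_dem": 31, "n_female": 28, "n_male": 30,
     "platform": "mass_spec"},
    {"study": "ADNI", "role": "validation", "country": "USA, Canada",
     "n_total": 702, "aneg_tneg": 289, "apos_tpos": 413,
     "aneg_tneg_cu": 123, "apos_tpos_ci": 368, "apos_tpos_mci": 226,
     "apos_tpos_dem": 142, "n_female": 299, "n_male": 398,
     "platform": "aptamer"},
    {"study": "Bangs", "role": "validation", "country": "USA",
     "n_total": 431, "aneg_tneg": 213, "apos_tpos": 218,
     "aneg_tneg_cu": 150, "apos_tpos_ci": 214, "apos_tpos_mci": 92,
     "apos_tpos_dem": 122, "n_female": 267, "n_male": 164,
     "platform": "mass_spec"},
    {"study": "Johnson", "role": "validation", "country": "USA",
     "n_total": 65, "aneg_tneg": 32, "apos_tpos": 33,
     "aneg_tneg_cu": 32, "apos_tpos_ci": 33, "apos_tpos_mci": null,
     "apos_tpos_dem": 33, "n_female": 32, "n_male": 26,
     "platform": "mass_spec"},
    {"study": "PPMI", "role": "differential",
     "country": "multi-national", "n_total": 798, "aneg_tneg": 184,
     "apos_tpos": null, "aneg_tneg_cu": null, "apos_tpos_ci": null,
     "apos_tpos_mci": null, "apos_tpos_dem": null, "n_female": 312,
     "n_male": 486, "platform": "aptamer", "pd_n": 614,
     "note": "Parkinson's disease cohort; the non-control stratum is PD, not A+T+"}
  ],
  "totals": [
    {"role": "discovery", "n_total": 759, "aneg_tneg": 345,
     "apos_tpos": 414, "aneg_tneg_cu": 119, "apos_tpos_ci": 153,
     "apos_tpos_mci": 43, "apos_tpos_dem": 36, "n_female": 317,
     "n_male": 412},
    {"role": "training", "n_total": 118, "aneg_tneg": 51, "apos_tpos": 67,
     "aneg_tneg_cu": 20, "apos_tpos_ci": 38, "apos_tpos_mci": 7,
     "apos_tpos_dem": 31, "n_female": 52, "n_male": 66},
    {"role": "validation", "n_total": 1198, "aneg_tneg": 534,
     "apos_tpos": 664, "aneg_tneg_cu": 305, "apos_tpos_ci": 615,
     "apos_tpos_mci": 318, "apos_tpos_dem": 297, "n_female": 598,
     "n_male": 588},
    {"role": "differential", "n_total": 798, "aneg_tneg": 184,
     "apos_tpos": null, "aneg_tneg_cu": null, "apos_tpos_ci": null,
     "apos_tpos_mci": null, "apos_tpos_dem": null, "n_female": 312,
     "n_male": 486}
  ]
}
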