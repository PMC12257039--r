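# Synthetic default parameter set for the tumor-agnostic entrectinib-style
# evaluation. Structure mirrors the published study design (nine indications,
# 121 basket-trial patients, weekly cycles, 10-year horizon, 1.5% discount,
# WTP thresholds of CAD 50,000 and 100,000 per QALY); the per-indication
# values are plausibility-checked SYNTHETIC stand-ins, not transcriptions of
# any HTA document, so absolute results illustrate the machinery only.
# Durations in weeks; money in 2021 CAD; per-cycle costs per weekly cycle.
# No distributions block: default assumed families are attached at load time
# (gamma for costs, lognormal for medians, beta for utilities).
time_unit: weeks
derive_other_care_costs: true
globals:
  utility_pf: 0.75
  utility_pd: 0.55
  discount_rate: 0.015
  cycle_length: 1.0
  horizon: 521.7857142857143
  wtp_thresholds: [50000.0, 100000.0]
  exchange_rate: 1.25349
  restriction_time: 130.0
  n_psa: 1000
  seed: 20210101
indications:
  - name: breast
    prevalence_weight: 0.25
    ntrk_prevalence: 0.0005
    trial_n: 7
    median_os_tx: 130.0
    median_pfs_tx: 65.0
    median_os_soc: 104.0
    median_pfs_soc: 39.0
    median_ttd: 35.0
    cost_pf_care: 160.0
    cost_pd_care: 520.0
    cost_ae_tx: 3100.0
    cost_ae_soc: 2300.0
    cost_drug_tx_cycle: 1925.0
    cost_admin_tx_cycle: 45.0
    cost_drug_soc_cycle: 350.0
    cost_ngs_panel: 2790.0
  - name: colorectal
    prevalence_weight: 0.20
    ntrk_prevalence: 0.002
    trial_n: 10
    median_os_tx: 70.0
    median_pfs_tx: 35.0
    median_os_soc: 52.0
    median_pfs_soc: 22.0
    median_ttd: 26.0
    cost_pf_care: 185.0
    cost_pd_care: 560.0
    cost_ae_tx: 3100.0
    cost_ae_soc: 2600.0
    cost_drug_tx_cycle: 1925.0
    cost_admin_tx_cycle: 45.0
    cost_drug_soc_cycle: 450.0
    cost_ngs_panel: 2790.0
  - name: NSCLC
    prevalence_weight: 0.15
    ntrk_prevalence: 0.002
    trial_n: 22
    median_os_tx: 126.0
    median_pfs_tx: 61.0
    median_os_soc: 61.0
    median_pfs_soc: 26.0
    median_ttd: 48.0
    cost_pf_care: 175.0
    cost_pd_care: 600.0
    cost_ae_tx: 3100.0
    cost_ae_soc: 2900.0
    cost_drug_tx_cycle: 1925.0
    cost_admin_tx_cycle: 45.0
    cost_drug_soc_cycle: 700.0
    cost_ngs_panel: 2790.0
  - name: pancreatic
    prevalence_weight: 0.08
    ntrk_prevalence: 0.003
    trial_n: 4
    median_os_tx: 43.0
    median_pfs_tx: 22.0
    median_os_soc: 30.0
    median_pfs_soc: 15.0
    median_ttd: 17.0
    cost_pf_care: 205.0
    cost_pd_care: 650.0
    cost_ae_tx: 3100.0
    cost_ae_soc: 2700.0
    cost_drug_tx_cycle: 1925.0
    cost_admin_tx_cycle: 45.0
    cost_drug_soc_cycle: 400.0
    cost_ngs_panel: 2790.0
  - name: thyroid
    prevalence_weight: 0.05
    ntrk_prevalence: 0.02
    trial_n: 8
    median_os_tx: 156.0
    median_pfs_tx: 87.0
    median_os_soc: 139.0
    median_pfs_soc: 70.0
    median_ttd: 52.0
    cost_pf_care: 140.0
    cost_pd_care: 430.0
    cost_ae_tx: 3100.0
    cost_ae_soc: 2100.0
    cost_drug_tx_cycle: 1925.0
    cost_admin_tx_cycle: 45.0
    cost_drug_soc_cycle: 250.0
    cost_ngs_panel: 2790.0
  - name: sarcoma
    prevalence_weight: 0.10
    ntrk_prevalence: 0.01
    trial_n: 33
    median_os_tx: 87.0
    median_pfs_tx: 48.0
    median_os_soc: 61.0
    median_pfs_soc: 26.0
    median_ttd: 39.0
    cost_pf_care: 170.0
    cost_pd_care: 540.0
    cost_ae_tx: 3100.0
    cost_ae_soc: 2500.0
    cost_drug_tx_cycle: 1925.0
    cost_admin_tx_cycle: 45.0
    cost_drug_soc_cycle: 500.0
    cost_ngs_panel: 2790.0
  - name: neuroendocrine
    prevalence_weight: 0.05
    ntrk_prevalence: 0.003
    trial_n: 5
    median_os_tx: 52.0
    median_pfs_tx: 26.0
    median_os_soc: 43.0
    median_pfs_soc: 22.0
    median_ttd: 22.0
    cost_pf_care: 165.0
    cost_pd_care: 500.0
    cost_ae_tx: 3100.0
    cost_ae_soc: 2400.0
    cost_drug_tx_cycle: 1925.0
    cost_admin_tx_cycle: 45.0
    cost_drug_soc_cycle: 300.0
    cost_ngs_panel: 2790.0
  - name: MASC
    prevalence_weight: 0.02
    ntrk_prevalence: 0.90
    trial_n: 24
    median_os_tx: 200.0
    median_pfs_tx: 113.0
    median_os_soc: 122.0
    median_pfs_soc: 52.0
    median_ttd: 61.0
    cost_pf_care: 130.0
    cost_pd_care: 420.0
    cost_ae_tx: 3100.0
    cost_ae_soc: 2000.0
    cost_drug_tx_cycle: 1925.0
    cost_admin_tx_cycle: 45.0
    cost_drug_soc_cycle: 200.0
    cost_ngs_panel: 2790.0
  - name: other
    prevalence_weight: 0.10
    ntrk_prevalence: 0.005
    trial_n: 8
    median_os_tx: 78.0
    median_pfs_tx: 43.0
    median_os_soc: 57.0
    median_pfs_soc: 26.0
    median_ttd: 30.0
    # care costs are derived at load time as the prevalence-weighted
    # average of the other indications (derive_other_care_costs above);
    # the values here are placeholders
    cost_pf_care: 170.0
    cost_pd_care: 540.0
    cost_ae_tx: 3100.0
    cost_ae_soc: 2500.0
    cost_drug_tx_cycle: 1925.0
    cost_admin_tx_cycle: 45.0
    cost_drug_soc_cycle: 400.0
    cost_ngs_panel: 2790.0
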