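# Example run configuration: five ALK inhibitors x two effusion events
# over an 11-year receipt-date window, exercised on a simulated
# spontaneous-report population with one injected association.
input_dir: quarters
output_dir: out

drugs:
  CRIZOTINIB: [XALKORI]
  CERITINIB: [ZYKADIA]
  ALECTINIB: [ALECENSA]
  BRIGATINIB: [ALUNBRIG]
  LORLATINIB: [LORBRENA, LORVIQUA]

events:
  Pleural effusion: [Pleural effusion]
  Pericardial effusion: [Pericardial effusion]

window:
  start: 2013-01-01
  end: 2023-12-31

criteria:
  min_ror: 2.00
  min_ci_low: 1.00
  min_reports: 10
  z_quantile: 1.959964

require_primary_suspect: true

simulate:
  n_reports: 20000
  drug_probs:
    CRIZOTINIB: 0.01
    CERITINIB: 0.01
    ALECTINIB: 0.01
    BRIGATINIB: 0.01
    LORLATINIB: 0.01
  event_probs:
    Pleural effusion: 0.010
    Pericardial effusion: 0.005
  injected:
    - {drug: CRIZOTINIB, event: Pleural effusion, or: 8}
  duplicate_rate: 0.10
  secondary_role_rate: 0.10
  n_quarters: 4
  seed: 1
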