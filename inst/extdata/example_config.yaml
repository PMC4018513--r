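# Example run configuration for run_pipeline() / `hdxflow run`.
# Paths are resolved relative to the working directory.
reference: maps/reference.mzXML
fasta: protein.fasta
msms_list: confirmed_peptides.txt   # optional
# control: maps/full_deuterated.mzXML   # optional 100% control
output_dir: results
deuterated:
  - { time: 15,   replicate: 1, path: maps/t15_r1.mzXML }
  - { time: 15,   replicate: 2, path: maps/t15_r2.mzXML }
  - { time: 60,   replicate: 1, path: maps/t60_r1.mzXML }
  - { time: 300,  replicate: 1, path: maps/t300_r1.mzXML }
  - { time: 1200, replicate: 1, path: maps/t1200_r1.mzXML }
params:
  detect:
    snr_threshold: 3
    charge_min: 1
    charge_max: 6
  assign:
    precision_ppm: 4
    wide_ppm: 30
  align:
    n_segments: 8
    tolerance_floor_s: 10
  deut:
    min_consecutive: 3
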