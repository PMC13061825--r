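# goodness-of-fit run configuration
mode: gof
data: observations.tsv
model: model_onefactor.yaml
methods: [pEBA4_RLS, SB, RLS]
seed: 1
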