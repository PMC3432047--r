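# Carbon-source scan baseline: each source normalized to 1 mmol carbon
# atoms per gDW per hour; NGAM refitted for the scan (0.67).
name: carbon_scan
ngam: 0.67
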