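model_id,exact,partial,no_match,researcher_segment
chatgpt_5,31,2,0,1
qualigpt,45,3,2,5
claude_4_sonnet,71,0,0,8
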