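code,human_analyst_1,human_analyst_2,chatgpt_5,claude_4_sonnet,qualigpt
Desire for personalisation,4,5,4,3,3
Truth and misinformation,4,5,4,4,4
Harm from generic advice,5,4,4,4,1
Need for flexibility and adaption,3,3,5,5,5
NHS lack of personalisation,2,4,4,3,5
Difficulty accessing healthcare,4,5,5,5,5
Care continuity/fragmentation,5,3,5,1,4
Desire for personalisation in AI interactions,3,4,4,3,3
Need for human and social interaction,4,4,2,4,5
Opinions of communities and peer support,3,4,4,5,3
Feedback on AI development,3,4,3,3,5
Scepticism surrounding security,4,5,4,5,5
Scepticism of medical experts,4,2,5,2,4
Peer support,3,5,4,4,3
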