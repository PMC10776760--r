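"chain_id","retelling_index","producer","condition","word_count","verb","adverb","noun","adjective","pronoun","preposition","negation","other"
"ex_human",0,"human","mildly_sad",154,32,10,25,9,25,27,2,24
"ex_human",1,"human","mildly_sad",62,16,2,11,7,10,6,1,9
"ex_human",2,"human","mildly_sad",71,15,0,12,7,12,12,0,13
"ex_human",3,"human","mildly_sad",56,12,2,11,2,10,11,0,8
"ex_llm",0,"llm","mildly_sad",154,32,10,25,9,25,27,2,24
"ex_llm",1,"llm","mildly_sad",53,11,4,11,5,4,10,0,8
"ex_llm",2,"llm","mildly_sad",43,10,3,9,4,6,8,0,3
"ex_llm",3,"llm","mildly_sad",51,12,2,10,4,9,10,0,4
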